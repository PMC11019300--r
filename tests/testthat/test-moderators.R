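test_that("subgroup analysis partitions Q and detects no difference when none", {
  # identical pooled estimates in both levels: Q_between = 0, p = 1
  e <- make_effects(c(0.2, 0.2, 0.2, 0.2), c(0.01, 0.02, 0.01, 0.02),
                    zone = c("a", "a", "b", "b"))
  sg <- subgroup_analysis(e, "zone")
  expect_equal(sg$Q_between, 0, tolerance = 1e-20)
  expect_equal(sg$p_subgroup, 1)

  # hand-set {A, A, B}: brute-force partition Q_total - sum(Q_within)
  e2 <- make_effects(c(0.1, 0.4, -0.3), c(0.02, 0.05, 0.01),
                     g = c("A", "A", "B"))
  sg2 <- subgroup_analysis(e2, "g")
  bA <- brute_pool_fixed(c(0.1, 0.4), c(0.02, 0.05))
  ball <- brute_pool_fixed(e2$lrr, e2$v)
  expect_equal(sg2$Q_between, ball$Q - bA$Q, tolerance = 1e-12)  # Q_within(B) = 0
  expect_equal(sg2$levels$n, c(2L, 1L))
  expect_true(sg2$levels$flagged[2])   # singleton level flagged
})

test_that("Q-partition identity holds on randomized subgroup fixtures", {
  set.seed(41)
  for (i in 1:30) {
    k <- sample(6:20, 1)
    m <- sample(2:4, 1)
    e <- random_effects(k)
    e$g <- sample(letters[1:m], k, replace = TRUE)
    if (length(unique(e$g)) < 2) next
    sg <- subgroup_analysis(e, "g")
    expect_equal(sg$Q_between + sg$Q_within, sg$Q_total, tolerance = 1e-8)
  }
})

test_that("subgroup analysis validates its inputs", {
  e <- make_effects(c(0.1, 0.2), c(0.01, 0.01), g = c("a", "a"))
  expect_error(subgroup_analysis(e, "g"), "single observed level")
  expect_error(subgroup_analysis(e, "nope"), "not found")
  e$g <- c("a", NA)
  expect_error(expect_warning(subgroup_analysis(e, "g"), "dropping"),
               "single observed level")
})

test_that("meta-regression solves the weighted normal equations", {
  # all equal responses: slope exactly 0
  e0 <- make_effects(rep(0.3, 5), runif(5, 0.01, 0.05), x = 1:5)
  mr0 <- meta_regression(e0, "x")
  expect_equal(mr0$coefficients$estimate[2], 0, tolerance = 1e-14)

  # two points: interpolation, zero residual
  e2 <- make_effects(c(0.1, 0.5), c(0.02, 0.03), x = c(1, 3))
  mr2 <- meta_regression(e2, "x")
  expect_equal(mr2$coefficients$estimate, c(-0.1, 0.2), tolerance = 1e-12)
  expect_equal(mr2$QE, 0, tolerance = 1e-20)

  # four hand-set points with unequal weights vs brute-force Cramer solution
  y <- c(0.12, -0.3, 0.45, 0.02); x <- c(0, 2, 5, 7)
  v <- c(0.01, 0.04, 0.002, 0.08)
  mr <- meta_regression(make_effects(y, v, x = x), "x")
  b <- brute_wls(y, x, 1 / v)
  expect_equal(mr$coefficients$estimate, c(b$intercept, b$slope), tolerance = 1e-10)
  expect_equal(mr$coefficients$se, c(b$se_intercept, b$se_slope), tolerance = 1e-10)
  # and vs the standard WLS fit
  lmfit <- lm(y ~ x, weights = 1 / v)
  expect_equal(unname(mr$coefficients$estimate), unname(coef(lmfit)),
               tolerance = 1e-10)
})

test_that("meta-regression matches metafor's fixed and MoM mixed fits", {
  set.seed(42)
  e <- random_effects(12)
  e$x <- runif(12, 0, 10)
  mr_f <- meta_regression(e, "x", method = "fixed_wls")
  rma_f <- metafor::rma(yi = e$lrr, vi = e$v, mods = ~e$x, method = "FE")
  expect_equal(mr_f$coefficients$estimate, as.numeric(rma_f$beta), tolerance = 1e-9)
  expect_equal(mr_f$coefficients$se, rma_f$se, tolerance = 1e-9)
  expect_equal(mr_f$QE, rma_f$QE, tolerance = 1e-9)

  mr_m <- meta_regression(e, "x", method = "mixed_mom")
  rma_m <- metafor::rma(yi = e$lrr, vi = e$v, mods = ~e$x, method = "DL")
  expect_equal(mr_m$tau2, rma_m$tau2, tolerance = 1e-8)
  expect_equal(mr_m$coefficients$estimate, as.numeric(rma_m$beta), tolerance = 1e-8)
})

test_that("meta-regression degenerate designs error rather than fit silently", {
  e <- make_effects(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01), x = c(2, 2, 2))
  expect_error(meta_regression(e, "x"), "constant")
  expect_error(meta_regression(e, "missing_col"), "not found")
  e$x2 <- c(1, NA, 3)
  expect_error(meta_regression(e, "x2"), "missing")
})

test_that("intercept-only meta-regression reproduces fixed-effect pooling", {
  set.seed(43)
  e <- random_effects(9)
  mr <- meta_regression(e, covariate = NULL)
  pf <- pool_fixed(e)
  expect_equal(mr$coefficients$estimate[1], pf$estimate, tolerance = 1e-12)
  expect_equal(mr$coefficients$se[1], pf$se, tolerance = 1e-12)
})

test_that("centering the covariate moves the intercept but not the slope", {
  set.seed(44)
  e <- random_effects(10)
  e$x <- runif(10, 0, 12)
  e$xc <- e$x - mean(e$x)
  m1 <- meta_regression(e, "x")
  m2 <- meta_regression(e, "xc")
  expect_equal(m1$coefficients$estimate[2], m2$coefficients$estimate[2],
               tolerance = 1e-10)
  expect_equal(m1$coefficients$se[2], m2$coefficients$se[2], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(m1$coefficients$estimate[1],
                                m2$coefficients$estimate[1])))
})

test_that("binary-moderator subgroup test equals the dummy-coded QM", {
  set.seed(45)
  e <- random_effects(11)
  e$g <- sample(c("x", "y"), 11, replace = TRUE)
  e$dummy <- as.numeric(e$g == "y")
  sg <- subgroup_analysis(e, "g")
  mr <- meta_regression(e, "dummy", method = "fixed_wls")
  expect_equal(sg$Q_between, mr$QM, tolerance = 1e-10)
})

test_that("cross-response regression joins on comparison_id and refuses tiny joins", {
  ids <- sprintf("p%02d", 1:8)
  ex <- make_effects(seq(-0.5, 0.9, length.out = 8), rep(0.01, 8),
                     comparison_id = ids)
  ey <- make_effects(-0.75 * ex$lrr, rep(0.02, 8), comparison_id = ids)
  cr <- cross_response_regression(ey, ex)
  expect_equal(cr$n_pairs, 8)
  expect_equal(cr$coefficients$estimate[2], -0.75, tolerance = 1e-12)
  expect_equal(cr$QE, 0, tolerance = 1e-16)

  # four joined pairs: below the default minimum
  expect_error(cross_response_regression(ey[1:4, ], ex),
               "4 comparison\\(s\\).*at least 5")
  # but allowed when the caller lowers the bar explicitly
  cr4 <- cross_response_regression(ey[1:4, ], ex, min_pairs = 3L)
  expect_equal(cr4$n_pairs, 4)
})

test_that("cross-response slope CI covers zero at the nominal rate under the null", {
  set.seed(46)
  hits <- 0; reps <- 400
  for (r in 1:reps) {
    ids <- sprintf("p%02d", 1:10)
    ex <- make_effects(rnorm(10, 0, 0.4), runif(10, 0.005, 0.05),
                       comparison_id = ids)
    # outcome unrelated to covariate: truth slope = 0
    ey <- make_effects(rnorm(10, 0, sqrt(0.02)), rep(0.02, 10),
                       comparison_id = ids)
    cr <- cross_response_regression(ey, ex)
    sl <- cr$coefficients[cr$coefficients$term == "slope", ]
    if (sl$ci_low <= 0 && 0 <= sl$ci_high) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.91)
  expect_lt(hits / reps, 0.99)
})

test_that("bubble export carries points, weights and a finite CI band", {
  set.seed(47)
  e <- random_effects(8)
  e$x <- runif(8, 0, 10)
  bd <- bubble_data(meta_regression(e, "x"))
  expect_equal(nrow(bd$points), 8)
  expect_equal(bd$points$weight, 1 / e$v)
  expect_true(all(bd$line$ci_low <= bd$line$fitted))
  expect_true(all(bd$line$ci_high >= bd$line$fitted))
  expect_equal(range(bd$line$covariate), range(e$x))
})
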