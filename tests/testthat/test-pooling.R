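test_that("fixed-effect pooling matches hand-summed oracles", {
  # single effect: estimate and SE are the effect's own
  p1 <- pool_fixed(make_effects(0.3, 0.01))
  expect_equal(p1$estimate, 0.3)
  expect_equal(p1$se, 0.1)
  expect_equal(p1$k, 1L)
  expect_equal(p1$I2, 0)

  # two effects, equal variance, symmetric: estimate 0
  p2 <- pool_fixed(make_effects(c(-0.2, 0.2), c(0.05, 0.05)))
  expect_equal(p2$estimate, 0, tolerance = 1e-15)

  # three effects, hand-summed inverse-variance arithmetic
  p3 <- pool_fixed(make_effects(c(0.1, 0.5, 0.3), c(0.04, 0.01, 0.02)))
  expect_equal(p3$estimate, (2.5 + 50 + 15) / (25 + 100 + 50), tolerance = 1e-12)
  expect_equal(p3$se, 1 / sqrt(175), tolerance = 1e-12)
  expect_equal(p3$ci_low, p3$estimate - 1.96 * p3$se)
  expect_equal(p3$ci_high, p3$estimate + 1.96 * p3$se)
  expect_equal(p3$percent_change, (exp(p3$estimate) - 1) * 100)
})

test_that("pooling errors on empty sets and non-positive variances", {
  expect_error(pool_fixed(make_effects(numeric(0), numeric(0))), "at least 1")
  expect_error(pool_fixed(make_effects(0.2, 0)), "> 0")
  expect_error(pool_random(make_effects(0.3, 0.01)), "at least 2")
  expect_error(heterogeneity(make_effects(0.3, 0.01)), "at least 2")
})

test_that("heterogeneity statistics follow the Q / I2 definitions", {
  # identical effects: Q = 0, I2 = 0
  h0 <- heterogeneity(make_effects(rep(0.25, 5), runif(5, 0.01, 0.05)))
  expect_equal(h0$Q, 0, tolerance = 1e-20)
  expect_equal(h0$I2, 0)
  expect_equal(h0$p, 1)

  # direct substitution: Q = 20 on df = 10 gives I2 = 50%
  expect_equal(grazemeta:::.i_squared(20, 10), 50)
  expect_equal(grazemeta:::.i_squared(5, 10), 0)   # truncated at zero

  set.seed(21)
  e <- random_effects(8)
  h <- heterogeneity(e)
  b <- brute_pool_fixed(e$lrr, e$v)
  expect_equal(h$Q, b$Q, tolerance = 1e-12)
  expect_equal(h$I2, b$I2, tolerance = 1e-12)
  expect_equal(h$p, pchisq(b$Q, 7, lower.tail = FALSE))
})

test_that("DerSimonian-Laird tau2 reduces to its equal-variance closed form", {
  set.seed(22)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    v <- runif(1, 0.005, 0.05)
    y <- rnorm(k, 0, 0.4)
    p <- pool_random(make_effects(y, rep(v, k)))
    # equal v: tau2 = max(0, sample variance - v)
    expect_equal(p$tau2, max(0, var(y) - v), tolerance = 1e-10)
  }
})

test_that("random-effects pooling truncates to the fixed fit when Q <= df", {
  e <- make_effects(c(0.30, 0.31, 0.29, 0.30), rep(0.5, 4))  # tiny Q, huge v
  pf <- pool_fixed(e); pr <- pool_random(e)
  expect_equal(pr$tau2, 0)
  expect_equal(pr$estimate, pf$estimate, tolerance = 1e-14)
  expect_equal(pr$se, pf$se, tolerance = 1e-14)
})

test_that("pooling agrees with metafor on randomized instances", {
  set.seed(23)
  for (i in 1:10) {
    e <- random_effects(sample(3:15, 1))
    fe <- metafor::rma(yi = e$lrr, vi = e$v, method = "FE")
    re <- metafor::rma(yi = e$lrr, vi = e$v, method = "DL")
    pf <- pool_fixed(e); pr <- pool_random(e)
    expect_equal(pf$estimate, as.numeric(fe$beta), tolerance = 1e-9)
    expect_equal(pf$se, fe$se, tolerance = 1e-9)
    expect_equal(pf$Q, fe$QE, tolerance = 1e-9)
    expect_equal(pr$tau2, re$tau2, tolerance = 1e-8)
    expect_equal(pr$estimate, as.numeric(re$beta), tolerance = 1e-8)
  }
})

test_that("pooling invariants hold on randomized instances", {
  set.seed(24)
  for (i in 1:25) {
    e <- random_effects(sample(2:12, 1))
    pf <- pool_fixed(e)
    w <- 1 / e$v
    expect_equal(sum(w / sum(w)), 1)                        # weight normalization
    expect_gte(pf$estimate, min(e$lrr))                     # convexity
    expect_lte(pf$estimate, max(e$lrr))
    expect_true(pf$ci_low <= pf$estimate && pf$estimate <= pf$ci_high)
    pr <- pool_random(e)
    if (pr$tau2 > 0) {
      expect_gt(pr$ci_high - pr$ci_low, pf$ci_high - pf$ci_low)
    }
    # adding a comparison at the pooled estimate: estimate fixed, SE shrinks
    e2 <- rbind(e[, c("lrr", "v", "comparison_id")],
                data.frame(lrr = pf$estimate, v = 0.02, comparison_id = "new"))
    pf2 <- pool_fixed(e2)
    expect_equal(pf2$estimate, pf$estimate, tolerance = 1e-12)
    expect_lt(pf2$se, pf$se)
  }
})

test_that("significance requires both p < .05 and a CI clear of zero", {
  sig <- pool_fixed(make_effects(c(0.4, 0.45, 0.42), rep(0.005, 3)))
  expect_true(sig$significant)
  null <- pool_fixed(make_effects(c(0.02, -0.03, 0.01), rep(0.01, 3)))
  expect_false(null$significant)
})

test_that("forest export keeps input order and appends matching summary rows", {
  set.seed(25)
  e <- random_effects(6)
  fd <- forest_data(e, model = "both")
  expect_equal(nrow(fd), 8)
  expect_equal(fd$label[1:6], e$comparison_id)
  expect_equal(fd$lrr[1:6], e$lrr)
  expect_equal(fd$ci_low[1:6], e$lrr - 1.96 * sqrt(e$v))
  expect_equal(sum(fd$weight_pct[fd$type == "comparison"]), 100, tolerance = 1e-9)
  pf <- pool_fixed(e)
  expect_equal(fd$lrr[fd$label == "summary_fixed"], pf$estimate)
  expect_equal(fd$ci_low[fd$label == "summary_fixed"], pf$ci_low)
})
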