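# Small in-code fixtures shared across test files.

# minimal effects table from raw (lrr, v) vectors
make_effects <- function(lrr, v, comparison_id = NULL, ...) {
  df <- data.frame(lrr = lrr, v = v, stringsAsFactors = FALSE)
  df$comparison_id <- if (is.null(comparison_id)) {
    sprintf("e%02d", seq_along(lrr))
  } else comparison_id
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# one complete comparison record, overridable field by field
make_record <- function(...) {
  rec <- data.frame(
    comparison_id = "c1", study_id = "s1",
    response_variable = "species_richness",
    mean_excl = 12, sd_excl = 2.5, se_excl = NA_real_, n_excl = 5L,
    mean_graz = 15, sd_graz = 3.0, se_graz = NA_real_, n_graz = 5L,
    duration_years = 2, climatic_zone = "subtropical",
    grazing_intensity = "high", grazing_history = "short",
    herbivore_type = "cattle", grassland_type = "tall_grassland",
    dispersion_source_excl = NA_character_,
    dispersion_source_graz = NA_character_,
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

# random (lrr, v) instance for oracle-equivalence loops
random_effects <- function(k, lrr_sd = 0.5, v_range = c(0.001, 0.1)) {
  make_effects(
    lrr = rnorm(k, 0, lrr_sd),
    v = runif(k, v_range[1], v_range[2])
  )
}

# brute-force fixed-effect pooling by explicit summation (independent of
# the package's vectorized path)
brute_pool_fixed <- function(lrr, v) {
  sw <- 0; swy <- 0
  for (i in seq_along(lrr)) {
    sw <- sw + 1 / v[i]
    swy <- swy + lrr[i] / v[i]
  }
  est <- swy / sw
  Q <- 0
  for (i in seq_along(lrr)) Q <- Q + (lrr[i] - est)^2 / v[i]
  list(est = est, se = sqrt(1 / sw), Q = Q,
       I2 = if (length(lrr) >= 2 && Q > 0) max(0, (Q - (length(lrr) - 1)) / Q) * 100 else 0)
}

# brute-force DerSimonian-Laird tau2 and random-effects pooling
brute_pool_random <- function(lrr, v) {
  f <- brute_pool_fixed(lrr, v)
  w <- 1 / v
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (f$Q - (length(lrr) - 1)) / C)
  ws <- 1 / (v + tau2)
  list(tau2 = tau2, est = sum(ws * lrr) / sum(ws), se = sqrt(1 / sum(ws)))
}

# brute-force 2-coefficient weighted least squares via Cramer's rule
brute_wls <- function(y, x, w) {
  s_w <- sum(w); s_x <- sum(w * x); s_xx <- sum(w * x^2)
  s_y <- sum(w * y); s_xy <- sum(w * x * y)
  det <- s_w * s_xx - s_x^2
  b1 <- (s_w * s_xy - s_x * s_y) / det
  b0 <- (s_y - b1 * s_x) / s_w
  # (X'WX)^-1 diagonal
  se0 <- sqrt(s_xx / det)
  se1 <- sqrt(s_w / det)
  list(intercept = b0, slope = b1, se_intercept = se0, se_slope = se1)
}
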