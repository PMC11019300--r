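#' Fixed-effect (inverse-variance) pooling of log response ratios
#'
#' Combines per-comparison effect sizes into the weighted mean response
#' ratio `RR++ = sum(w * lrr) / sum(w)` with weights `w = 1/v`, so that
#' comparisons with more precise estimates carry more weight. The weighted
#' standard error is `S(RR++) = sqrt(1 / sum(w))`, the 95% confidence
#' interval `RR++ +/- 1.96 * S(RR++)`, and the two-sided p-value comes from
#' the normal deviate `z = RR++ / S(RR++)`. Heterogeneity is summarized by
#' Cochran's `Q = sum(w * (lrr - RR++)^2)` on `k - 1` degrees of freedom
#' and by `I2 = max(0, (Q - df) / Q) * 100`, the percentage of variation
#' across comparisons due to heterogeneity rather than chance.
#'
#' An effect is flagged `significant` only when both conditions hold:
#' p < .05 and the 95% CI excludes zero.
#'
#' @param effects Effects table from [effect_sizes()] (needs columns
#'   `lrr` and `v`; all `v > 0`).
#' @return An object of class `grazemeta_pool`: a list with `estimate`,
#'   `se`, `ci_low`, `ci_high`, `z`, `p`, `k`, `Q`, `df`, `p_Q`, `I2`,
#'   `tau2` (0 for the fixed-effect model), `model`, `percent_change`,
#'   `significant`.
#' @seealso [pool_random()], [heterogeneity()]
#' @export
pool_fixed <- function(effects) {
  effects <- .check_effects(effects, k_min = 1L, caller = "pool_fixed")
  w <- 1 / effects$v
  est <- sum(w * effects$lrr) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- nrow(effects)
  Q <- sum(w * (effects$lrr - est)^2)
  df <- k - 1L
  .pool_result(est, se, k, Q, df, tau2 = 0, model = "fixed")
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Estimates the between-comparison variance `tau2` by the
#' DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))`
#' computed from the fixed-effect weights `w = 1/v`, then re-pools with
#' `w* = 1 / (v + tau2)`. When `Q <= df` the estimate truncates to zero and
#' the result coincides with [pool_fixed()]. Heterogeneity statistics
#' (`Q`, `I2`) are always reported from the fixed-effect weights.
#'
#' @inheritParams pool_fixed
#' @return An object of class `grazemeta_pool` (see [pool_fixed()]), with
#'   `model = "random"` and the estimated `tau2`.
#' @export
pool_random <- function(effects) {
  effects <- .check_effects(effects, k_min = 2L, caller = "pool_random")
  w <- 1 / effects$v
  est_f <- sum(w * effects$lrr) / sum(w)
  k <- nrow(effects)
  Q <- sum(w * (effects$lrr - est_f)^2)
  df <- k - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  ws <- 1 / (effects$v + tau2)
  est <- sum(ws * effects$lrr) / sum(ws)
  se <- sqrt(1 / sum(ws))
  .pool_result(est, se, k, Q, df, tau2 = tau2, model = "random")
}

#' Heterogeneity statistics for a set of effect sizes
#'
#' Cochran's Q (inverse-variance weighted sum of squared deviations from
#' the pooled estimate), its chi-square p-value on `k - 1` degrees of
#' freedom, and Higgins & Thompson's I-squared.
#'
#' @inheritParams pool_fixed
#' @return A list with `Q`, `df`, `I2` (percent) and `p`.
#' @export
heterogeneity <- function(effects) {
  effects <- .check_effects(effects, k_min = 2L, caller = "heterogeneity")
  w <- 1 / effects$v
  est <- sum(w * effects$lrr) / sum(w)
  Q <- sum(w * (effects$lrr - est)^2)
  df <- nrow(effects) - 1L
  list(Q = Q, df = df, I2 = .i_squared(Q, df),
       p = pchisq(Q, df = df, lower.tail = FALSE))
}

.i_squared <- function(Q, df) {
  if (df < 1L || Q <= 0) return(0)
  max(0, (Q - df) / Q) * 100
}

.pool_result <- function(est, se, k, Q, df, tau2, model) {
  ci_low <- est - .GM_Z95 * se
  ci_high <- est + .GM_Z95 * se
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  res <- list(
    estimate = est, se = se, ci_low = ci_low, ci_high = ci_high,
    z = z, p = p, k = k,
    Q = Q, df = df,
    p_Q = if (df >= 1L) pchisq(Q, df = df, lower.tail = FALSE) else NA_real_,
    I2 = .i_squared(Q, df),
    tau2 = tau2, model = model,
    percent_change = percent_change(est),
    significant = (p < 0.05) && (ci_low > 0 || ci_high < 0)
  )
  class(res) <- "grazemeta_pool"
  res
}

#' @export
print.grazemeta_pool <- function(x, digits = 4, ...) {
  cat(sprintf("%s-effect pooled log response ratio (k = %d)\n",
              x$model, x$k))
  cat(sprintf("  RR++ = %.*f  (95%% CI %.*f to %.*f),  SE = %.*f\n",
              digits, x$estimate, digits, x$ci_low, digits, x$ci_high,
              digits, x$se))
  cat(sprintf("  z = %.3f, p = %.4g, %ssignificant (p < .05 and CI excludes 0)\n",
              x$z, x$p, if (x$significant) "" else "not "))
  cat(sprintf("  percent change = %.1f%%\n", x$percent_change))
  if (x$df >= 1L) {
    cat(sprintf("  heterogeneity: Q = %.2f (df = %d, p = %.4g), I2 = %.1f%%, tau2 = %.4f\n",
                x$Q, x$df, x$p_Q, x$I2, x$tau2))
  }
  invisible(x)
}

#' Forest-plot data for a set of effect sizes
#'
#' Per-comparison log response ratios with 95% CIs (LRR +/- 1.96*sqrt(v)),
#' in input order, followed by summary row(s) for the requested model(s).
#' This is the plot-ready table behind a standard forest plot; no plot is
#' drawn.
#'
#' @inheritParams pool_fixed
#' @param model `"fixed"`, `"random"`, or `"both"` summary rows.
#' @return A `data.frame` with columns `label`, `type` (`"comparison"` or
#'   `"summary"`), `lrr`, `ci_low`, `ci_high`, `weight_pct` (percent of
#'   total fixed-effect weight).
#' @export
forest_data <- function(effects, model = c("fixed", "random", "both")) {
  model <- match.arg(model)
  effects <- .check_effects(effects, k_min = 1L, caller = "forest_data")
  w <- 1 / effects$v
  lab <- if (!is.null(effects$comparison_id)) as.character(effects$comparison_id)
         else paste0("row_", seq_len(nrow(effects)))
  rows <- data.frame(
    label = lab, type = "comparison",
    lrr = effects$lrr,
    ci_low = effects$lrr - .GM_Z95 * sqrt(effects$v),
    ci_high = effects$lrr + .GM_Z95 * sqrt(effects$v),
    weight_pct = 100 * w / sum(w),
    stringsAsFactors = FALSE
  )
  summaries <- list()
  if (model %in% c("fixed", "both")) summaries <- c(summaries, list(pool_fixed(effects)))
  if (model %in% c("random", "both") && nrow(effects) >= 2L) {
    summaries <- c(summaries, list(pool_random(effects)))
  }
  for (s in summaries) {
    rows <- rbind(rows, data.frame(
      label = paste0("summary_", s$model), type = "summary",
      lrr = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high,
      weight_pct = 100, stringsAsFactors = FALSE
    ))
  }
  rownames(rows) <- NULL
  rows
}
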