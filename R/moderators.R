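#' Subgroup analysis with a between-groups heterogeneity test
#'
#' Pools effect sizes separately within each level of a categorical
#' moderator and tests whether the levels differ, by partitioning
#' Cochran's Q under the shared fixed-effect weights:
#' `Q_between = sum_g W_g * (est_g - est_overall)^2`, where `W_g` is the
#' summed weight of level g. Under the common-weight scheme
#' `Q_total = Q_between + sum_g Q_within_g` holds exactly, and `Q_between`
#' is chi-square on `m - 1` degrees of freedom under the null of no
#' subgroup differences.
#'
#' Level estimates and CIs are reported for the requested `model`; the
#' between-groups test always uses the fixed-effect partition (a
#' random-effects partition would break the identity above).
#'
#' @param effects Effects table from [effect_sizes()].
#' @param moderator Name of a categorical column of `effects`.
#' @param model Pool each level with the `"fixed"` or `"random"` model.
#' @return An object of class `grazemeta_subgroup`: list with `moderator`,
#'   `model`, `levels` (data.frame: level, n, estimate, se, ci_low,
#'   ci_high, I2, tau2, flagged), `Q_between`, `df_between`, `p_subgroup`,
#'   `Q_total`, `Q_within`.
#' @export
subgroup_analysis <- function(effects, moderator, model = c("fixed", "random")) {
  model <- match.arg(model)
  effects <- .check_effects(effects, k_min = 2L, caller = "subgroup_analysis")
  if (is.null(effects[[moderator]])) {
    stop("subgroup_analysis: moderator column '", moderator,
         "' not found in effects table", call. = FALSE)
  }
  g <- as.character(effects[[moderator]])
  keep <- !is.na(g)
  if (any(!keep)) {
    warning("subgroup_analysis: dropping ", sum(!keep),
            " effect(s) with missing '", moderator, "'")
    effects <- effects[keep, , drop = FALSE]
    g <- g[keep]
  }
  lev <- unique(g)
  if (length(lev) < 2L) {
    stop("subgroup_analysis: moderator '", moderator,
         "' has a single observed level; nothing to contrast", call. = FALSE)
  }

  w <- 1 / effects$v
  est_all <- sum(w * effects$lrr) / sum(w)
  Q_total <- sum(w * (effects$lrr - est_all)^2)

  rows <- vector("list", length(lev))
  Q_between <- 0
  Q_within <- 0
  for (i in seq_along(lev)) {
    sel <- g == lev[i]
    sub <- effects[sel, , drop = FALSE]
    pooled <- if (model == "random" && nrow(sub) >= 2L) pool_random(sub) else pool_fixed(sub)
    w_g <- sum(1 / sub$v)
    est_g <- sum((1 / sub$v) * sub$lrr) / w_g          # fixed, for the partition
    Q_between <- Q_between + w_g * (est_g - est_all)^2
    Q_within <- Q_within + sum((1 / sub$v) * (sub$lrr - est_g)^2)
    rows[[i]] <- data.frame(
      level = lev[i], n = nrow(sub),
      estimate = pooled$estimate, se = pooled$se,
      ci_low = pooled$ci_low, ci_high = pooled$ci_high,
      I2 = pooled$I2, tau2 = pooled$tau2,
      flagged = nrow(sub) == 1L,      # singleton levels: estimate = the one lrr
      stringsAsFactors = FALSE
    )
  }
  df_between <- length(lev) - 1L
  res <- list(
    moderator = moderator, model = model,
    levels = do.call(rbind, rows),
    Q_between = Q_between, df_between = df_between,
    p_subgroup = pchisq(Q_between, df = df_between, lower.tail = FALSE),
    Q_total = Q_total, Q_within = Q_within
  )
  class(res) <- "grazemeta_subgroup"
  res
}

#' @export
print.grazemeta_subgroup <- function(x, digits = 3, ...) {
  cat(sprintf("Subgroup analysis by '%s' (%s-effect level estimates)\n",
              x$moderator, x$model))
  print(format(x$levels, digits = digits), row.names = FALSE)
  cat(sprintf("Between groups: Q = %.3f (df = %d), p = %.4g\n",
              x$Q_between, x$df_between, x$p_subgroup))
  invisible(x)
}

# internal weighted-least-squares core used by meta_regression and
# cross_response_regression; X is the design matrix, w the weights
.wls_fit <- function(y, X, w) {
  XtW <- t(X * w)
  xtwx <- XtW %*% X
  if (abs(det(xtwx)) < .Machine$double.eps * max(abs(xtwx))^ncol(X) * 1e4) {
    stop("meta_regression: rank-deficient design (constant covariate?)",
         call. = FALSE)
  }
  vcov <- solve(xtwx)
  beta <- drop(vcov %*% (XtW %*% y))
  fitted <- drop(X %*% beta)
  QE <- sum(w * (y - fitted)^2)
  list(beta = beta, vcov = vcov, fitted = fitted, QE = QE)
}

#' Weighted meta-regression of log response ratios on a covariate
#'
#' Regresses per-comparison LRRs on a single continuous covariate (e.g.
#' exclusion duration in years) by weighted least squares on the design
#' `[1, x]`. Weights are the fixed-effect `1/v` (`method = "fixed_wls"`)
#' or `1/(v + tau2)` with a method-of-moments residual heterogeneity
#' estimate (`method = "mixed_mom"`, the meta-analytic mixed-effects
#' model). Coefficient covariance comes from the weighted normal
#' equations, `(X'WX)^-1`; 95% CIs are `coef +/- 1.96 * SE`. The model /
#' residual decomposition `QM` / `QE` is reported, with `QE` chi-square on
#' `k - 2` df under homogeneity about the regression line.
#'
#' @param effects Effects table from [effect_sizes()].
#' @param covariate Name of a numeric column of `effects` (or `NULL` for
#'   an intercept-only fit, which reproduces [pool_fixed()]).
#' @param method `"fixed_wls"` or `"mixed_mom"`.
#' @return An object of class `grazemeta_metareg`: list with `covariate`,
#'   `method`, `k`, `coefficients` (data.frame: term, estimate, se,
#'   ci_low, ci_high, z, p), `QM`, `QE`, `df_QE`, `tau2`, and the joined
#'   model frame in `data`.
#' @export
meta_regression <- function(effects, covariate,
                            method = c("fixed_wls", "mixed_mom")) {
  method <- match.arg(method)
  effects <- .check_effects(effects, k_min = 2L, caller = "meta_regression")
  k <- nrow(effects)
  if (is.null(covariate)) {
    X <- matrix(1, nrow = k, ncol = 1, dimnames = list(NULL, "intercept"))
    x <- NULL
  } else {
    if (is.null(effects[[covariate]])) {
      stop("meta_regression: covariate column '", covariate, "' not found",
           call. = FALSE)
    }
    x <- effects[[covariate]]
    if (!is.numeric(x) || anyNA(x)) {
      stop("meta_regression: covariate must be numeric with no missing values",
           call. = FALSE)
    }
    if (length(unique(x)) < 2L) {
      stop("meta_regression: rank-deficient design, covariate '", covariate,
           "' is constant", call. = FALSE)
    }
    X <- cbind(intercept = 1, slope = x)
  }
  y <- effects$lrr
  w <- 1 / effects$v
  fit <- .wls_fit(y, X, w)
  tau2 <- 0
  if (method == "mixed_mom") {
    # method-of-moments residual heterogeneity: E[QE] = (k - p) + tau2 * tr(P)
    W <- diag(w, nrow = k)
    P <- W - W %*% X %*% fit$vcov %*% t(X) %*% W
    tau2 <- max(0, (fit$QE - (k - ncol(X))) / sum(diag(P)))
    w <- 1 / (effects$v + tau2)
    fit <- .wls_fit(y, X, w)
  }
  se <- sqrt(diag(fit$vcov))
  est <- fit$beta
  coefs <- data.frame(
    term = colnames(X), estimate = est, se = se,
    ci_low = est - .GM_Z95 * se, ci_high = est + .GM_Z95 * se,
    z = est / se, p = 2 * pnorm(-abs(est / se)),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  # QM: drop in weighted SS relative to the intercept-only fit (same weights)
  wmean <- sum(w * y) / sum(w)
  QM <- sum(w * (y - wmean)^2) - fit$QE
  res <- list(
    covariate = covariate, method = method, k = k,
    coefficients = coefs, QM = QM, QE = fit$QE, df_QE = k - ncol(X),
    tau2 = tau2,
    data = data.frame(lrr = y, v = effects$v, w = w,
                      covariate = if (is.null(x)) NA_real_ else x,
                      fitted = fit$fitted)
  )
  class(res) <- "grazemeta_metareg"
  res
}

#' @export
print.grazemeta_metareg <- function(x, digits = 4, ...) {
  cat(sprintf("Meta-regression of LRR on %s (%s, k = %d",
              if (is.null(x$covariate)) "intercept only" else x$covariate,
              x$method, x$k))
  if (x$tau2 > 0) cat(sprintf(", tau2 = %.4f", x$tau2))
  cat(")\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("QM = %.3f; QE = %.3f (df = %d, p = %.4g)\n",
              x$QM, x$QE, x$df_QE,
              pchisq(x$QE, df = x$df_QE, lower.tail = FALSE)))
  invisible(x)
}

#' Regression of one response's LRR on another's
#'
#' Joins two effect-size tables on `comparison_id` (same site, duration
#' and intensity) and regresses the outcome LRR on the covariate LRR with
#' the outcome's inverse variances as weights — e.g. the change in species
#' richness against the change in aboveground biomass under exclusion.
#' Refuses to fit when fewer than `min_pairs` comparisons measured both
#' responses, since slopes from a handful of points are uninterpretable.
#'
#' @param effects_y Effects table for the outcome response variable.
#' @param effects_x Effects table for the covariate response variable.
#' @param min_pairs Minimum number of joined pairs (default 5).
#' @param method Passed to [meta_regression()].
#' @return A `grazemeta_metareg` object with an extra `n_pairs` element
#'   and the joined ids in `pair_ids`.
#' @export
cross_response_regression <- function(effects_y, effects_x, min_pairs = 5L,
                                      method = c("fixed_wls", "mixed_mom")) {
  method <- match.arg(method)
  effects_y <- .check_effects(effects_y, k_min = 1L, caller = "cross_response_regression")
  effects_x <- .check_effects(effects_x, k_min = 1L, caller = "cross_response_regression")
  if (is.null(effects_y$comparison_id) || is.null(effects_x$comparison_id)) {
    stop("cross_response_regression: both tables need a comparison_id column",
         call. = FALSE)
  }
  ids <- intersect(effects_y$comparison_id, effects_x$comparison_id)
  if (length(ids) < min_pairs) {
    stop(sprintf(
      paste0("cross_response_regression: only %d comparison(s) measured both ",
             "responses; at least %d required for an interpretable slope"),
      length(ids), min_pairs), call. = FALSE)
  }
  iy <- match(ids, effects_y$comparison_id)
  ix <- match(ids, effects_x$comparison_id)
  joined <- data.frame(
    comparison_id = ids,
    lrr = effects_y$lrr[iy], v = effects_y$v[iy],
    lrr_x = effects_x$lrr[ix],
    stringsAsFactors = FALSE
  )
  res <- meta_regression(joined, "lrr_x", method = method)
  res$n_pairs <- length(ids)
  res$pair_ids <- ids
  res
}

#' Bubble-plot data for a meta-regression
#'
#' Per-point LRR, covariate value and weight (points are drawn with size
#' proportional to weight), plus fitted-line and 95% confidence-band
#' coordinates over a covariate grid. Plot-ready; no plot is drawn.
#'
#' @param fit A `grazemeta_metareg` object with a covariate.
#' @param n_grid Number of grid points for the fitted line.
#' @return A list with `points` (lrr, covariate, weight) and `line`
#'   (covariate, fitted, ci_low, ci_high) data.frames.
#' @export
bubble_data <- function(fit, n_grid = 50L) {
  if (!inherits(fit, "grazemeta_metareg")) {
    stop("bubble_data: expected a grazemeta_metareg object", call. = FALSE)
  }
  if (is.null(fit$covariate) || all(is.na(fit$data$covariate))) {
    stop("bubble_data: fit has no covariate", call. = FALSE)
  }
  pts <- data.frame(
    lrr = fit$data$lrr, covariate = fit$data$covariate, weight = fit$data$w
  )
  grid <- seq(min(pts$covariate), max(pts$covariate), length.out = n_grid)
  Xg <- cbind(1, grid)
  beta <- fit$coefficients$estimate
  # vcov on the weighted normal equations, reconstructed from the SEs and
  # the stored model frame
  X <- cbind(1, fit$data$covariate)
  vcov <- solve(t(X * fit$data$w) %*% X)
  pred <- drop(Xg %*% beta)
  band <- sqrt(rowSums((Xg %*% vcov) * Xg))
  line <- data.frame(
    covariate = grid, fitted = pred,
    ci_low = pred - .GM_Z95 * band, ci_high = pred + .GM_Z95 * band
  )
  list(points = pts, line = line)
}
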