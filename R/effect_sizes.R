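#' Log response ratio
#'
#' The effect size for one paired grazed-vs-excluded comparison:
#' `LRR = ln(Xt / Xc)`, where `Xt` is the mean under grazing exclusion and
#' `Xc` the mean under grazing. The LRR is symmetric around zero,
#' scale-invariant, and approximately normal when both means are positive
#' and well away from zero.
#'
#' @param mean_excl Mean of the response under exclusion (treatment, `Xt`);
#'   must be strictly positive.
#' @param mean_graz Mean under grazing (control, `Xc`); strictly positive.
#' @return Numeric vector of log response ratios.
#' @examples
#' log_response_ratio(10, 10)          # 0: no effect
#' log_response_ratio(8, 10)           # ln(0.8)
#' @export
log_response_ratio <- function(mean_excl, mean_graz) {
  if (!is.numeric(mean_excl) || !is.numeric(mean_graz)) {
    stop("means must be numeric", call. = FALSE)
  }
  if (any(!is.finite(mean_excl)) || any(!is.finite(mean_graz))) {
    stop("means must be finite", call. = FALSE)
  }
  if (any(mean_excl <= 0) || any(mean_graz <= 0)) {
    stop("log response ratio requires strictly positive means in both arms",
         call. = FALSE)
  }
  log(mean_excl / mean_graz)
}

#' Sampling variance of the log response ratio
#'
#' `v = st^2 / (nt * Xt^2) + sc^2 / (nc * Xc^2)`: the delta-method variance
#' of `ln(Xt/Xc)` from the two arms' standard deviations, sample sizes and
#' means. Zero only when both standard deviations are zero.
#'
#' @param sd_excl,sd_graz Arm standard deviations (`st`, `sc`), `>= 0`.
#' @param n_excl,n_graz Arm sample sizes (`nt`, `nc`), `>= 1`.
#' @param mean_excl,mean_graz Arm means (`Xt`, `Xc`), strictly positive.
#' @return Numeric vector of variances.
#' @examples
#' lrr_variance(2, 4, 10, 3, 9, 12)  # 4/400 + 9/1296
#' @export
lrr_variance <- function(sd_excl, n_excl, mean_excl, sd_graz, n_graz, mean_graz) {
  args <- list(sd_excl, n_excl, mean_excl, sd_graz, n_graz, mean_graz)
  if (!all(vapply(args, is.numeric, logical(1)))) {
    stop("all arguments must be numeric", call. = FALSE)
  }
  if (any(mean_excl <= 0) || any(mean_graz <= 0)) {
    stop("lrr_variance requires strictly positive means", call. = FALSE)
  }
  if (any(sd_excl < 0) || any(sd_graz < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (any(n_excl < 1) || any(n_graz < 1)) {
    stop("sample sizes must be >= 1", call. = FALSE)
  }
  sd_excl^2 / (n_excl * mean_excl^2) + sd_graz^2 / (n_graz * mean_graz^2)
}

#' Percent change implied by a pooled log response ratio
#'
#' Back-transforms a (pooled) LRR to the percentage change of the response
#' under exclusion relative to grazing: `(exp(estimate) - 1) * 100`.
#'
#' @param estimate Log response ratio (pooled or single), finite.
#' @return Percent change (e.g. `log(2)` maps to 100).
#' @export
percent_change <- function(estimate) {
  if (!is.numeric(estimate) || any(!is.finite(estimate))) {
    stop("estimate must be finite numeric", call. = FALSE)
  }
  (exp(estimate) - 1) * 100
}

#' Per-comparison effect sizes from a comparison table
#'
#' Computes, for every row of a harmonized and dispersion-complete
#' comparison table, the log response ratio, its sampling variance `v` and
#' the inverse-variance weight `w = 1/v`, carrying the moderators through.
#'
#' Rows with `v = 0` (both arm SDs zero) would receive infinite weight and
#' are rejected: the dispersion-imputation ladder (mean/10 floor) makes
#' such rows unreachable in curated data, so their presence indicates a
#' data error.
#'
#' @param records Comparison table, e.g. from [read_comparisons()] after
#'   [impute_dispersion()].
#' @param bias_correct Apply the small-sample (delta-method) correction to
#'   the LRR and its variance? Off by default: the plain ratio is the
#'   standard estimator for this literature.
#' @return A `data.frame` of class `grazemeta_effects` with columns
#'   `comparison_id`, `study_id`, `response_variable`, `lrr`, `v`, `w`,
#'   plus all moderator columns present in `records`.
#' @export
effect_sizes <- function(records, bias_correct = FALSE) {
  records <- as.data.frame(records)
  needed <- c("comparison_id", "study_id", "response_variable",
              "mean_excl", "sd_excl", "n_excl",
              "mean_graz", "sd_graz", "n_graz")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    stop("effect_sizes: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(records$sd_excl) || anyNA(records$sd_graz)) {
    stop("effect_sizes: missing standard deviations; run impute_dispersion() first",
         call. = FALSE)
  }
  lrr <- log_response_ratio(records$mean_excl, records$mean_graz)
  v <- lrr_variance(records$sd_excl, records$n_excl, records$mean_excl,
                    records$sd_graz, records$n_graz, records$mean_graz)
  if (bias_correct) {
    # second-order delta-method correction for ln of a sample mean
    at <- records$sd_excl^2 / (records$n_excl * records$mean_excl^2)
    ac <- records$sd_graz^2 / (records$n_graz * records$mean_graz^2)
    lrr <- lrr + (at - ac) / 2
    v <- v + (at^2 + ac^2) / 2
  }
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop("effect_sizes: zero sampling variance in row(s) ",
         paste(bad, collapse = ", "),
         " (both arm SDs zero); such rows cannot be weighted", call. = FALSE)
  }
  mods <- setdiff(names(records),
                  c(needed, "se_excl", "se_graz",
                    "dispersion_source_excl", "dispersion_source_graz"))
  out <- data.frame(
    comparison_id = records$comparison_id,
    study_id = records$study_id,
    response_variable = records$response_variable,
    lrr = lrr, v = v, w = 1 / v,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, records[, mods, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("grazemeta_effects", "data.frame")
  out
}

# internal: validate an effects table for the pooling / moderator modules
.check_effects <- function(effects, k_min = 1L, caller = "pool") {
  effects <- as.data.frame(effects)
  for (col in c("lrr", "v")) {
    if (is.null(effects[[col]])) {
      stop(caller, ": effects table must have a '", col, "' column",
           call. = FALSE)
    }
  }
  k <- nrow(effects)
  if (k < k_min) {
    stop(caller, ": needs at least ", k_min, " effect size(s), got ", k,
         call. = FALSE)
  }
  if (any(!is.finite(effects$lrr)) || any(!is.finite(effects$v))) {
    stop(caller, ": non-finite lrr or v", call. = FALSE)
  }
  if (any(effects$v <= 0)) {
    stop(caller, ": all sampling variances must be > 0", call. = FALSE)
  }
  effects
}
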