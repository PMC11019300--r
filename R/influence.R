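# Sensitivity of pooled and meta-regression results to single comparisons.
#
# A single long-running exclosure can dominate a duration meta-regression:
# the diagnostics here refit the analysis with comparisons left out and flag
# those whose omission flips significance or shifts the headline estimate by
# more than a chosen multiple of its standard error.

# internal: build the refit closure for an analysis spec
.analysis_fun <- function(analysis, model, covariate, method) {
  if (analysis == "pooled") {
    if (model == "random") function(e) pool_random(e) else function(e) pool_fixed(e)
  } else {
    function(e) meta_regression(e, covariate, method = method)
  }
}

# internal: headline (estimate, ci_low, ci_high, significant) of a result
.headline <- function(res) {
  if (inherits(res, "grazemeta_pool")) {
    c(estimate = res$estimate, se = res$se,
      ci_low = res$ci_low, ci_high = res$ci_high,
      significant = as.numeric(res$significant))
  } else {
    co <- res$coefficients[res$coefficients$term == "slope", ]
    sig <- (co$p < 0.05) && (co$ci_low > 0 || co$ci_high < 0)
    c(estimate = co$estimate, se = co$se,
      ci_low = co$ci_low, ci_high = co$ci_high,
      significant = as.numeric(sig))
  }
}

#' Leave-one-out influence diagnostics
#'
#' Refits a pooled estimate or a duration meta-regression k times, each
#' time omitting one comparison, and flags comparisons whose omission
#' either flips the significance verdict (p < .05 with the 95% CI clear
#' of zero) or moves the headline estimate — the pooled LRR, or the slope
#' for a meta-regression — by more than `se_multiple` times the base
#' fit's standard error.
#'
#' @param effects Effects table from [effect_sizes()] (k >= 3).
#' @param analysis `"pooled"` or `"metareg"`.
#' @param model Pooling model when `analysis = "pooled"`.
#' @param covariate Covariate column when `analysis = "metareg"`.
#' @param method Meta-regression method (see [meta_regression()]).
#' @param se_multiple Estimate-shift threshold, in base-fit SEs (default 1).
#' @return Object of class `grazemeta_loo`: list with `base` (the full
#'   fit), `reps` (data.frame: omitted id, estimate, ci_low, ci_high,
#'   significant, shift_se), and `influence_flags` (ids flagged).
#' @export
leave_one_out <- function(effects, analysis = c("pooled", "metareg"),
                          model = c("fixed", "random"), covariate = NULL,
                          method = c("fixed_wls", "mixed_mom"),
                          se_multiple = 1) {
  analysis <- match.arg(analysis)
  model <- match.arg(model)
  method <- match.arg(method)
  effects <- .check_effects(effects, k_min = 3L, caller = "leave_one_out")
  if (analysis == "metareg" && is.null(covariate)) {
    stop("leave_one_out: metareg analysis needs a covariate", call. = FALSE)
  }
  fit_fun <- .analysis_fun(analysis, model, covariate, method)
  base <- fit_fun(effects)
  base_h <- .headline(base)
  ids <- if (!is.null(effects$comparison_id)) as.character(effects$comparison_id)
         else as.character(seq_len(nrow(effects)))
  reps <- vector("list", nrow(effects))
  for (i in seq_len(nrow(effects))) {
    h <- .headline(fit_fun(effects[-i, , drop = FALSE]))
    reps[[i]] <- data.frame(
      omitted = ids[i],
      estimate = h[["estimate"]], ci_low = h[["ci_low"]],
      ci_high = h[["ci_high"]], significant = h[["significant"]] == 1,
      shift_se = abs(h[["estimate"]] - base_h[["estimate"]]) / base_h[["se"]],
      stringsAsFactors = FALSE
    )
  }
  reps <- do.call(rbind, reps)
  flags <- reps$omitted[reps$shift_se > se_multiple |
                          reps$significant != (base_h[["significant"]] == 1)]
  res <- list(base = base, reps = reps, influence_flags = flags,
              analysis = analysis, se_multiple = se_multiple)
  class(res) <- "grazemeta_loo"
  res
}

#' @export
print.grazemeta_loo <- function(x, digits = 3, ...) {
  cat(sprintf("Leave-one-out over %d comparisons (%s analysis)\n",
              nrow(x$reps), x$analysis))
  cat(sprintf("Base estimate %.4f; flagged influential: %s\n",
              .headline(x$base)[["estimate"]],
              if (length(x$influence_flags) == 0) "none"
              else paste(x$influence_flags, collapse = ", ")))
  invisible(x)
}

#' Exclude comparisons by rule and refit
#'
#' Removes the comparisons matched by `rule` and refits the analysis,
#' returning the paired before/after results — e.g. excluding the study
#' with the longest exclusion duration and re-estimating the duration
#' slope. Ties on a max-duration rule exclude every tied comparison.
#'
#' @inheritParams leave_one_out
#' @param rule Either the string `"max-duration"` (exclude all comparisons
#'   tied at the maximum `duration_years`) or a predicate
#'   `function(effects) -> logical` marking rows to exclude.
#' @return List of class `grazemeta_exclusion`: `base`, `refit`,
#'   `excluded_ids`, and `flipped` (did the significance verdict change?).
#' @export
exclude_and_refit <- function(effects, rule = "max-duration",
                              analysis = c("pooled", "metareg"),
                              model = c("fixed", "random"), covariate = NULL,
                              method = c("fixed_wls", "mixed_mom")) {
  analysis <- match.arg(analysis)
  model <- match.arg(model)
  method <- match.arg(method)
  effects <- .check_effects(effects, k_min = 2L, caller = "exclude_and_refit")
  if (is.character(rule) && identical(rule, "max-duration")) {
    if (is.null(effects$duration_years)) {
      stop("exclude_and_refit: 'max-duration' rule needs a duration_years column",
           call. = FALSE)
    }
    sel <- effects$duration_years == max(effects$duration_years)
  } else if (is.function(rule)) {
    sel <- rule(effects)
    if (!is.logical(sel) || length(sel) != nrow(effects)) {
      stop("exclude_and_refit: rule must return one logical per row",
           call. = FALSE)
    }
  } else {
    stop("exclude_and_refit: rule must be \"max-duration\" or a predicate function",
         call. = FALSE)
  }
  if (!any(sel)) {
    stop("exclude_and_refit: exclusion rule matched no comparisons", call. = FALSE)
  }
  if (all(sel)) {
    stop("exclude_and_refit: exclusion rule matched every comparison", call. = FALSE)
  }
  if (sum(sel) > 1L) {
    message("exclude_and_refit: rule matched ", sum(sel), " tied comparisons; excluding all")
  }
  fit_fun <- .analysis_fun(analysis, model, covariate, method)
  base <- fit_fun(effects)
  refit <- fit_fun(effects[!sel, , drop = FALSE])
  ids <- if (!is.null(effects$comparison_id)) as.character(effects$comparison_id)
         else as.character(seq_len(nrow(effects)))
  res <- list(
    base = base, refit = refit, excluded_ids = ids[sel],
    flipped = .headline(base)[["significant"]] != .headline(refit)[["significant"]]
  )
  class(res) <- "grazemeta_exclusion"
  res
}

#' @export
print.grazemeta_exclusion <- function(x, ...) {
  b <- .headline(x$base); r <- .headline(x$refit)
  cat(sprintf("Excluded: %s\n", paste(x$excluded_ids, collapse = ", ")))
  cat(sprintf("  base : %.4f (%.4f, %.4f)%s\n", b[["estimate"]],
              b[["ci_low"]], b[["ci_high"]],
              if (b[["significant"]] == 1) " *" else ""))
  cat(sprintf("  refit: %.4f (%.4f, %.4f)%s\n", r[["estimate"]],
              r[["ci_low"]], r[["ci_high"]],
              if (r[["significant"]] == 1) " *" else ""))
  if (x$flipped) cat("  significance verdict flipped\n")
  invisible(x)
}
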