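#' Run the full exclusion meta-analysis pipeline
#'
#' Wires the stages end to end: read (or simulate) the comparison table,
#' impute missing dispersions, harmonize categories, compute effect sizes,
#' pool per response variable (fixed and/or random effects), run the
#' requested subgroup analyses and duration meta-regressions, the
#' richness-on-biomass cross-response regression when both variables are
#' present, and the max-duration exclusion sensitivity refit. All outputs
#' are written to `out_dir`:
#' `effects.csv`, `pooled.json`, `subgroups.json`, `metareg.json`,
#' `forest.csv`, `bubble.csv`, `sensitivity.json`, `validation.json` and
#' `manifest.json` (config echo, seed, package version, per-stage row
#' counts, warnings). The manifest suffices to re-run the identical
#' analysis.
#'
#' @param input A comparison table (data.frame), a path to a CSV in the
#'   [read_comparisons()] schema, or a [sim_config()] to simulate from.
#' @param out_dir Output directory; must not already contain a
#'   `manifest.json` unless `overwrite = TRUE`.
#' @param variables Response variables to analyze (default: all present).
#' @param model `"fixed"`, `"random"` or `"both"` (headline model is the
#'   fixed-effect fit; both are always computed when `"both"`).
#' @param moderators Categorical moderators for subgroup analysis.
#' @param covariates Numeric covariates for meta-regression.
#' @param min_pairs Minimum joined pairs for the cross-response
#'   regression.
#' @param sensitivity_rule Exclusion rule for [exclude_and_refit()]
#'   (default `"max-duration"`), or `NULL` to skip.
#' @param seed Seed recorded in the manifest (and used when `input` is a
#'   sim config, overriding its `seed` field).
#' @param overwrite Allow writing into a directory with existing results?
#' @param verbose Log stage progress to stderr?
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(input, out_dir,
                         variables = NULL,
                         model = c("both", "fixed", "random"),
                         moderators = c("climatic_zone", "grazing_intensity"),
                         covariates = "duration_years",
                         min_pairs = 5L,
                         sensitivity_rule = "max-duration",
                         seed = 1L,
                         overwrite = FALSE,
                         verbose = FALSE) {
  model <- match.arg(model)
  say <- function(...) if (verbose) message("run_pipeline: ", sprintf(...))
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  } else if (file.exists(file.path(out_dir, "manifest.json")) && !overwrite) {
    stop("run_pipeline: '", out_dir,
         "' already holds results; use overwrite = TRUE to replace them",
         call. = FALSE)
  }

  # --- stage: input -------------------------------------------------------
  if (inherits(input, "sim_config")) {
    input$seed <- as.integer(seed)
    say("simulating comparison table (seed %d)", seed)
    records <- generate_comparisons(input)
    input_desc <- list(type = "simulated", config = unclass(input))
  } else if (is.character(input) && length(input) == 1L) {
    say("reading %s", input)
    records <- read_comparisons(input)
    input_desc <- list(type = "file", path = normalizePath(input))
  } else if (is.data.frame(input)) {
    records <- as.data.frame(input)
    input_desc <- list(type = "data.frame")
  } else {
    stop("run_pipeline: input must be a data.frame, a CSV path, or a sim_config",
         call. = FALSE)
  }
  report <- validate_comparisons(records)

  # --- stage: impute + harmonize -----------------------------------------
  say("imputing dispersions and harmonizing categories")
  records <- impute_dispersion(records)
  records <- harmonize_categories(records)

  # --- stage: effect sizes ------------------------------------------------
  effects <- effect_sizes(records)
  if (is.null(variables)) variables <- unique(effects$response_variable)
  missing_vars <- setdiff(variables, effects$response_variable)
  if (length(missing_vars) > 0) {
    stop("run_pipeline: requested variable(s) absent from data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  for (m in moderators) {
    if (is.null(effects[[m]])) {
      stop("run_pipeline: requested moderator column absent from data: ", m,
           call. = FALSE)
    }
  }
  for (cv in covariates) {
    if (is.null(effects[[cv]])) {
      stop("run_pipeline: requested covariate column absent from data: ", cv,
           call. = FALSE)
    }
  }
  write.csv(effects, file.path(out_dir, "effects.csv"), row.names = FALSE)

  pool_one <- function(e, which) {
    if (which == "random" && nrow(e) >= 2L) pool_random(e) else pool_fixed(e)
  }
  models <- if (model == "both") c("fixed", "random") else model

  pooled <- list()
  forest <- list()
  subgroups <- list()
  metareg <- list()
  bubbles <- list()
  sensitivity <- list()

  for (rv in variables) {
    e <- effects[effects$response_variable == rv, , drop = FALSE]
    say("pooling %s (k = %d)", rv, nrow(e))
    pooled[[rv]] <- lapply(setNames(models, models),
                           function(mm) unclass(pool_one(e, mm)))
    fd <- forest_data(e, model = model)
    fd$response_variable <- rv
    forest[[rv]] <- fd

    for (m in moderators) {
      lev <- unique(e[[m]][!is.na(e[[m]])])
      if (length(lev) < 2L) {
        note(sprintf("subgroup %s/%s skipped: single observed level", rv, m))
        next
      }
      sg <- subgroup_analysis(e, m, model = if (model == "random") "random" else "fixed")
      subgroups[[rv]][[m]] <- list(
        moderator = m, levels = sg$levels,
        Q_between = sg$Q_between, df_between = sg$df_between,
        p_subgroup = sg$p_subgroup
      )
    }

    for (cv in covariates) {
      if (nrow(e) < 3L || length(unique(e[[cv]])) < 2L) {
        note(sprintf("meta-regression %s/%s skipped: too few points or constant covariate",
                     rv, cv))
        next
      }
      mr <- meta_regression(e, cv)
      metareg[[rv]][[cv]] <- list(
        covariate = cv, k = mr$k, coefficients = mr$coefficients,
        QM = mr$QM, QE = mr$QE, df_QE = mr$df_QE
      )
      bd <- bubble_data(mr)
      bd$points$response_variable <- rv
      bd$points$covariate_name <- cv
      bubbles[[paste(rv, cv, sep = ".")]] <- bd$points

      if (!is.null(sensitivity_rule) && nrow(e) >= 3L &&
            sum(e[[cv]] == max(e[[cv]])) < nrow(e)) {
        ex <- exclude_and_refit(e, rule = sensitivity_rule,
                                analysis = "metareg", covariate = cv)
        sensitivity[[paste(rv, cv, sep = ".")]] <- list(
          analysis = "metareg", covariate = cv,
          excluded = ex$excluded_ids, flipped = ex$flipped,
          base = .headline(ex$base), refit = .headline(ex$refit)
        )
      }
    }
  }

  # cross-response regression: richness LRR on biomass LRR
  cross <- NULL
  if (all(c("species_richness", "aboveground_biomass") %in% variables)) {
    ey <- effects[effects$response_variable == "species_richness", ]
    ex <- effects[effects$response_variable == "aboveground_biomass", ]
    n_pairs <- length(intersect(ey$comparison_id, ex$comparison_id))
    if (n_pairs >= min_pairs && n_pairs >= 3L) {
      cr <- cross_response_regression(ey, ex, min_pairs = min_pairs)
      cross <- list(outcome = "species_richness",
                    covariate = "aboveground_biomass",
                    n_pairs = cr$n_pairs, coefficients = cr$coefficients,
                    QM = cr$QM, QE = cr$QE)
    } else {
      note(sprintf("cross-response regression skipped: %d joined pair(s) < %d",
                   n_pairs, min_pairs))
    }
  }

  # --- stage: outputs -----------------------------------------------------
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows", na = "null")
  wj(pooled, "pooled.json")
  wj(subgroups, "subgroups.json")
  wj(c(metareg, list(cross_response = cross)), "metareg.json")
  wj(sensitivity, "sensitivity.json")
  wj(report, "validation.json")
  write.csv(do.call(rbind, forest), file.path(out_dir, "forest.csv"),
            row.names = FALSE)
  if (length(bubbles) > 0) {
    write.csv(do.call(rbind, bubbles), file.path(out_dir, "bubble.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("grazemeta")),
    seed = as.integer(seed),
    input = input_desc,
    settings = list(variables = variables, model = model,
                    moderators = moderators, covariates = covariates,
                    min_pairs = min_pairs,
                    sensitivity_rule = if (is.null(sensitivity_rule)) NULL
                                       else as.character(sensitivity_rule)),
    counts = list(
      n_records = nrow(records),
      n_studies = length(unique(records$study_id)),
      n_comparisons = length(unique(records$comparison_id)),
      k_per_variable = as.list(table(effects$response_variable))
    ),
    warnings = warnings_log,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  wj(manifest, "manifest.json")
  say("done; outputs in %s", out_dir)
  invisible(manifest)
}
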