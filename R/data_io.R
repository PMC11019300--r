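# Reading, validating and harmonizing comparison tables.
#
# The on-disk format is a UTF-8, comma-separated CSV with one header row and
# one row per (comparison x response variable). Required columns:
#   comparison_id, study_id, response_variable,
#   mean_excl, sd_excl, se_excl, n_excl,
#   mean_graz, sd_graz, se_graz, n_graz,
#   duration_years, climatic_zone, grazing_intensity, grazing_history,
#   herbivore_type, grassland_type
# Optional provenance columns dispersion_source_excl / dispersion_source_graz
# are filled by impute_dispersion(). Unknown columns are preserved untouched.

.GM_REQUIRED_COLS <- c(
  "comparison_id", "study_id", "response_variable",
  "mean_excl", "sd_excl", "se_excl", "n_excl",
  "mean_graz", "sd_graz", "se_graz", "n_graz",
  "duration_years", "climatic_zone", "grazing_intensity",
  "grazing_history", "herbivore_type", "grassland_type"
)
.GM_NUMERIC_COLS <- c("mean_excl", "sd_excl", "se_excl", "n_excl",
                      "mean_graz", "sd_graz", "se_graz", "n_graz",
                      "duration_years")

#' Read a comparison table from CSV
#'
#' Reads, types and validates a table of paired grazed-vs-excluded
#' comparisons. Errors name the offending row (file row, counting the
#' header as row 1) and column. Unknown columns are kept as opaque
#' metadata.
#'
#' @param path Path to a CSV file with the documented schema.
#' @return A `data.frame` of comparison records; zero rows (with a warning)
#'   if the file holds only a valid header.
#' @export
read_comparisons <- function(path) {
  if (!file.exists(path)) {
    stop("read_comparisons: file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = "character", check.names = TRUE)
  miss <- setdiff(.GM_REQUIRED_COLS, names(raw))
  if (length(miss) > 0) {
    stop("read_comparisons: schema error, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("read_comparisons: '", basename(path),
            "' contains a valid header but no records")
  }
  for (col in .GM_NUMERIC_COLS) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf(
        "read_comparisons: parse error, non-numeric value '%s' in column '%s', file row %d",
        vals[bad[1]], col, bad[1] + 1L), call. = FALSE)
    }
    raw[[col]] <- num
  }
  for (col in c("n_excl", "n_graz")) {
    if (all(is.na(raw[[col]]) | raw[[col]] == round(raw[[col]]))) {
      raw[[col]] <- as.integer(raw[[col]])
    }
  }
  validate_comparisons(raw)
  raw
}

#' Validate a comparison table
#'
#' Checks the invariants a comparison table must satisfy before effect
#' sizes can be computed: positive arm means (the log response ratio is
#' undefined otherwise), integer sample sizes of at least 1, non-negative
#' dispersions where present, and finite non-negative exclusion durations.
#'
#' @param records A comparison table (data.frame).
#' @return Invisibly, a validation report: a list with `n_records`,
#'   `n_studies`, `n_missing_sd`, and `problems` (empty when valid).
#'   Invalid tables raise an error naming the first offending row.
#' @export
validate_comparisons <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(.GM_REQUIRED_COLS, names(records))
  if (length(miss) > 0) {
    stop("validate_comparisons: schema error, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  .fail_row <- function(rows, what) {
    if (length(rows) > 0) {
      stop(sprintf("validate_comparisons: %s (record row %d)", what, rows[1]),
           call. = FALSE)
    }
  }
  .fail_row(which(is.na(records$mean_excl) | is.na(records$mean_graz)),
            "missing arm mean")
  .fail_row(which(records$mean_excl <= 0 | records$mean_graz <= 0),
            "non-positive arm mean; log response ratio undefined")
  .fail_row(which(is.na(records$n_excl) | is.na(records$n_graz) |
                    records$n_excl < 1 | records$n_graz < 1 |
                    records$n_excl != round(records$n_excl) |
                    records$n_graz != round(records$n_graz)),
            "sample sizes must be integers >= 1")
  .fail_row(which(!is.na(records$sd_excl) & records$sd_excl < 0),
            "negative sd_excl")
  .fail_row(which(!is.na(records$sd_graz) & records$sd_graz < 0),
            "negative sd_graz")
  .fail_row(which(is.na(records$duration_years) | records$duration_years < 0 |
                    !is.finite(records$duration_years)),
            "duration_years must be finite and >= 0")
  .fail_row(which(!records$response_variable %in% .GM_VARIABLES),
            paste0("response_variable must be one of: ",
                   paste(.GM_VARIABLES, collapse = ", ")))
  report <- list(
    n_records = nrow(records),
    n_studies = length(unique(records$study_id)),
    n_missing_sd = sum(is.na(records$sd_excl)) + sum(is.na(records$sd_graz)),
    problems = character(0)
  )
  invisible(report)
}

#' Impute missing standard deviations
#'
#' Applies, independently per arm, the dispersion-imputation ladder used
#' when field studies under-report variability:
#' \enumerate{
#'   \item SD reported: keep it (provenance `reported_sd`);
#'   \item else SE reported: `SD = SE * sqrt(n)` with that arm's own `n`
#'     (provenance `from_se`);
#'   \item else: `SD = mean / 10` (provenance `tenth_of_mean`).
#' }
#' After imputation both SD fields are present and each arm carries a
#' provenance flag, so sensitivity analyses can down-weight or drop the
#' `tenth_of_mean` rows. The operation is idempotent and never alters
#' means, sample sizes or moderators.
#'
#' @param records Comparison table.
#' @param verbose Log one message per imputed arm?
#' @return The table with `sd_excl` / `sd_graz` complete and
#'   `dispersion_source_excl` / `dispersion_source_graz` set.
#' @export
impute_dispersion <- function(records, verbose = FALSE) {
  records <- as.data.frame(records)
  for (arm in c("excl", "graz")) {
    sd_col <- paste0("sd_", arm)
    se_col <- paste0("se_", arm)
    n_col <- paste0("n_", arm)
    mean_col <- paste0("mean_", arm)
    src_col <- paste0("dispersion_source_", arm)
    if (is.null(records[[src_col]])) records[[src_col]] <- NA_character_
    sd <- records[[sd_col]]
    se <- if (is.null(records[[se_col]])) rep(NA_real_, nrow(records)) else records[[se_col]]
    src <- records[[src_col]]

    has_sd <- !is.na(sd)
    use_se <- !has_sd & !is.na(se)
    use_tenth <- !has_sd & is.na(se)

    src[has_sd & is.na(src)] <- "reported_sd"
    sd[use_se] <- se[use_se] * sqrt(records[[n_col]][use_se])
    src[use_se] <- "from_se"
    sd[use_tenth] <- records[[mean_col]][use_tenth] / 10
    src[use_tenth] <- "tenth_of_mean"

    if (verbose) {
      for (i in which(use_se | use_tenth)) {
        message(sprintf("impute_dispersion: row %d (%s), %s arm: sd <- %.6g [%s]",
                        i, records$comparison_id[i], arm, sd[i], src[i]))
      }
    }
    records[[sd_col]] <- sd
    records[[src_col]] <- src
  }
  records
}

#' Harmonize categorical moderators to the closed vocabularies
#'
#' Applies the category-conversion rules used when collating heterogeneous
#' study reports:
#' \itemize{
#'   \item grazing intensity: `extensive` is read as `low`, `overgrazing`
#'     as `high`; `low` / `moderate` / `high` pass through;
#'   \item grassland type: `Pampa`, `Jarillal`, `Mountain grassland` and
#'     `Pastizal en filo` map to `tall_grassland`; `meadow` and `peatland`
#'     map to `bofedal`;
#'   \item evolutionary grazing history, when absent, is derived from
#'     geography: tropical sites dominated by camelids (llamas, alpacas,
#'     with their millennia-long Andean grazing history) are classed
#'     `long`; subtropical sites (European livestock, introduced within
#'     the last 500 years) are classed `short`.
#' }
#' Labels outside the accepted vocabulary raise an error listing it.
#'
#' @param records Comparison table.
#' @return The table with `grazing_intensity`, `grassland_type`,
#'   `climatic_zone` and `grazing_history` in closed vocabularies.
#' @export
harmonize_categories <- function(records) {
  records <- as.data.frame(records)

  map_closed <- function(x, map, keep, what) {
    x_l <- tolower(trimws(as.character(x)))
    out <- ifelse(x_l %in% names(map), unname(map[x_l]), x_l)
    bad <- which(!is.na(out) & !out %in% keep)
    if (length(bad) > 0) {
      stop(sprintf(
        "harmonize_categories: unmappable %s '%s' (row %d); accepted: %s",
        what, x[bad[1]], bad[1],
        paste(c(names(map), keep), collapse = ", ")), call. = FALSE)
    }
    out
  }

  records$grazing_intensity <- map_closed(
    records$grazing_intensity,
    c(extensive = "low", overgrazing = "high"),
    .GM_INTENSITIES, "grazing intensity")

  records$grassland_type <- map_closed(
    records$grassland_type,
    c("pampa" = "tall_grassland", "jarillal" = "tall_grassland",
      "mountain grassland" = "tall_grassland",
      "pastizal en filo" = "tall_grassland",
      "meadow" = "bofedal", "peatland" = "bofedal"),
    c("tall_grassland", "bofedal"), "grassland type")

  records$climatic_zone <- map_closed(
    records$climatic_zone, c(), .GM_ZONES, "climatic zone")

  hist <- tolower(trimws(as.character(records$grazing_history)))
  hist[hist == ""] <- NA_character_
  derive <- is.na(hist)
  if (any(derive)) {
    camelid <- grepl("camelid|llama|alpaca", tolower(records$herbivore_type))
    hist[derive & records$climatic_zone == "subtropical"] <- "short"
    hist[derive & records$climatic_zone == "tropical" & camelid] <- "long"
    left <- which(is.na(hist))
    if (length(left) > 0) {
      stop(sprintf(
        paste0("harmonize_categories: cannot derive grazing_history for row %d ",
               "(tropical, not camelid-dominated); supply 'short' or 'long' explicitly"),
        left[1]), call. = FALSE)
    }
  }
  bad <- which(!hist %in% .GM_HISTORIES)
  if (length(bad) > 0) {
    stop(sprintf(
      "harmonize_categories: unmappable grazing history '%s' (row %d); accepted: short, long",
      records$grazing_history[bad[1]], bad[1]), call. = FALSE)
  }
  records$grazing_history <- hist
  records
}

#' Write a comparison table to CSV
#'
#' Writes the documented schema; numeric values are rendered with 17
#' significant digits so that a write/read round trip preserves them
#' exactly. Missing values are written as empty fields.
#'
#' @param records Comparison table.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_comparisons <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      chr <- vapply(out[[col]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 17)
      }, character(1))
      out[[col]] <- chr
    }
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
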