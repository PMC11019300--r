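test_that("dispersion imputation follows the SD > SE > mean/10 ladder", {
  # reported SD: untouched
  r1 <- impute_dispersion(make_record(sd_excl = 3.1))
  expect_equal(r1$sd_excl, 3.1)
  expect_equal(r1$dispersion_source_excl, "reported_sd")

  # SE fallback uses the arm's own n: sd = se * sqrt(n)
  r2 <- impute_dispersion(make_record(sd_excl = NA_real_, se_excl = 2, n_excl = 4L))
  expect_equal(r2$sd_excl, 4)
  expect_equal(r2$dispersion_source_excl, "from_se")

  # final rung: one tenth of the arm mean
  r3 <- impute_dispersion(make_record(sd_graz = NA_real_, se_graz = NA_real_,
                                      mean_graz = 50))
  expect_equal(r3$sd_graz, 5)
  expect_equal(r3$dispersion_source_graz, "tenth_of_mean")
})

test_that("imputation is idempotent, per arm, and never touches other fields", {
  rec <- rbind(
    make_record(comparison_id = "a", sd_excl = NA_real_, se_excl = 1.5, n_excl = 9L),
    make_record(comparison_id = "b", sd_excl = NA_real_, se_excl = NA_real_,
                sd_graz = NA_real_, se_graz = NA_real_)
  )
  once <- impute_dispersion(rec)
  twice <- impute_dispersion(once)
  expect_identical(once, twice)
  # arms treated independently
  expect_equal(once$dispersion_source_excl, c("from_se", "tenth_of_mean"))
  expect_equal(once$dispersion_source_graz, c("reported_sd", "tenth_of_mean"))
  # untouched columns
  for (col in c("mean_excl", "mean_graz", "n_excl", "n_graz",
                "duration_years", "grazing_intensity")) {
    expect_identical(once[[col]], rec[[col]])
  }
})

test_that("category harmonization applies the documented conversions", {
  r <- make_record(grazing_intensity = "overgrazing")
  expect_equal(harmonize_categories(r)$grazing_intensity, "high")
  r <- make_record(grazing_intensity = "extensive")
  expect_equal(harmonize_categories(r)$grazing_intensity, "low")
  r <- make_record(grassland_type = "Pampa")
  expect_equal(harmonize_categories(r)$grassland_type, "tall_grassland")
  r <- make_record(grassland_type = "Pastizal en filo")
  expect_equal(harmonize_categories(r)$grassland_type, "tall_grassland")
  r <- make_record(grassland_type = "meadow")
  expect_equal(harmonize_categories(r)$grassland_type, "bofedal")
  expect_error(harmonize_categories(make_record(grazing_intensity = "severe")),
               "accepted")
  expect_error(harmonize_categories(make_record(grassland_type = "savanna")),
               "accepted")
})

test_that("grazing history is derived from zone and herbivore when absent", {
  r <- make_record(grazing_history = NA_character_, climatic_zone = "subtropical")
  expect_equal(harmonize_categories(r)$grazing_history, "short")
  r <- make_record(grazing_history = NA_character_, climatic_zone = "tropical",
                   herbivore_type = "camelid", grassland_type = "bofedal")
  expect_equal(harmonize_categories(r)$grazing_history, "long")
  r <- make_record(grazing_history = NA_character_, climatic_zone = "tropical",
                   herbivore_type = "cattle")
  expect_error(harmonize_categories(r), "cannot derive")
})

test_that("write/read round trip preserves every field exactly", {
  tab <- example_comparisons()
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparisons(tab, path)
  back <- read_comparisons(path)
  expect_equal(names(back), names(tab))
  for (col in names(tab)) {
    expect_identical(back[[col]], tab[[col]], label = paste("column", col))
  }
})

test_that("read_comparisons enforces the schema and row-level validity", {
  tab <- example_comparisons()
  path <- withr::local_tempfile(fileext = ".csv")

  # missing required column
  write.csv(tab[, setdiff(names(tab), "mean_graz")], path, row.names = FALSE)
  expect_error(read_comparisons(path), "schema error.*mean_graz")

  # non-numeric mean names row and column
  bad <- tab
  bad$mean_excl <- as.character(bad$mean_excl)
  bad$mean_excl[3] <- "twelve"
  write_comparisons_chr <- function(d, p) write.csv(d, p, row.names = FALSE, na = "")
  write_comparisons_chr(bad, path)
  expect_error(read_comparisons(path), "mean_excl.*row 4")

  # zero control mean is a validation error naming the row
  bad2 <- tab
  bad2$mean_graz[5] <- 0
  write_comparisons(bad2, path)
  expect_error(read_comparisons(path), "non-positive arm mean.*row 5")

  # header-only file: empty table plus a warning
  write.csv(tab[0, ], path, row.names = FALSE)
  expect_warning(empty <- read_comparisons(path), "no records")
  expect_equal(nrow(empty), 0)

  expect_error(read_comparisons(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("the example table has the documented composition", {
  tab <- example_comparisons()
  expect_equal(nrow(tab), 49)
  expect_equal(length(unique(tab$comparison_id)), 27)
  expect_equal(length(unique(tab$study_id)), 13)
  per_comp <- tab[!duplicated(tab$comparison_id), ]
  expect_equal(median(per_comp$duration_years), 2)
  expect_equal(range(per_comp$duration_years), c(0, 15))
  expect_equal(sum(tab$response_variable == "species_richness"), 15)
  expect_equal(sum(tab$response_variable == "shannon_diversity"), 15)
  expect_equal(sum(tab$response_variable == "aboveground_biomass"), 19)
  # dispersion under-reporting: 24 of 49 records lack an SD; 17 recover via
  # SE and 7 fall through to the mean/10 rule
  expect_equal(sum(is.na(tab$sd_excl)), 24)
  imp <- impute_dispersion(tab)
  expect_equal(sum(imp$dispersion_source_excl == "from_se"), 17)
  expect_equal(sum(imp$dispersion_source_excl == "tenth_of_mean"), 7)
  expect_false(anyNA(imp$sd_excl))
  expect_false(anyNA(imp$sd_graz))
})
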