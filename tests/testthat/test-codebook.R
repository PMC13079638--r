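test_that("packaged default codebook loads with the declared structure", {
  path <- system.file("extdata", "codebook_default.json", package = "ohsurvey")
  expect_no_warning(cb <- load_codebook(path))
  expect_s3_class(cb, "ohs_codebook")
  expect_identical(sum(cb$items$section == "symptom"), 66L)
  expect_identical(sum(cb$items$section == "risk"), 47L)
  expect_identical(sum(cb$items$section == "protection"), 26L)
  expect_length(cb$systems, 10)
  expect_setequal(unique(cb$items$domain[cb$items$section == "symptom"]),
                  cb$systems)
  expect_identical(cb$items, default_codebook()$items)
})

test_that("codebook validation rejects duplicate ids and bad scale bounds", {
  cb <- tiny_codebook()
  dup <- cb$items
  dup$id[2] <- dup$id[1]
  expect_error(codebook(dup, cb$systems, cb$risk_categories,
                        cb$protection_categories),
               "duplicate.*s_a1")
  bad <- cb$items
  bad$scale_max[bad$section == "symptom"][1] <- 5L
  expect_error(codebook(bad, cb$systems, cb$risk_categories,
                        cb$protection_categories),
               "scale 0..3.*s_a1")
  unmapped <- cb$items
  unmapped$domain[1] <- "Nonexistent system"
  expect_error(codebook(unmapped, cb$systems, cb$risk_categories,
                        cb$protection_categories),
               "outside the declared physiological systems")
})

test_that("survey CSV round-trips exactly through write and load", {
  cb <- tiny_codebook()
  ds <- tiny_survey(cb)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(ds, f)
  ds2 <- load_survey(f, cb)
  expect_identical(ds2$respondent_ids, ds$respondent_ids)
  expect_identical(ds2$symptoms, ds$symptoms)
  expect_identical(ds2$risks, ds$risks)
  expect_identical(ds2$protections, ds$protections)
  expect_identical(ds2$demographics, ds$demographics)
})

test_that("survey loading validates totally: ranges, columns, labels", {
  cb <- tiny_codebook()
  ds <- tiny_survey(cb)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(ds, f)
  # Out-of-range cell is named by item and row.
  tab <- read.csv(f, check.names = FALSE)
  tab$s_a1[2] <- 4
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, bad, row.names = FALSE)
  expect_error(load_survey(bad, cb), "out of range.*'s_a1'.*row.* 2")
  # Missing item column is listed.
  tab2 <- read.csv(f, check.names = FALSE)
  tab2$p_u <- NULL
  miss <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, miss, row.names = FALSE)
  expect_error(load_survey(miss, cb), "missing item columns: p_u")
  # Textual codes map through the scale of the item's section.
  tab3 <- read.csv(f, check.names = FALSE, colClasses = "character")
  tab3$s_a1[1] <- "mild"; tab3$r_x[1] <- "present"; tab3$p_u[1] <- "moderate"
  lab <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab3, lab, row.names = FALSE)
  ds3 <- load_survey(lab, cb)
  expect_identical(unname(ds3$symptoms[1, "s_a1"]), 1L)
  expect_identical(unname(ds3$risks[1, "r_x"]), 1L)
  expect_identical(unname(ds3$protections[1, "p_u"]), 2L)
  # Unknown columns are reported, not silently used.
  tab4 <- read.csv(f, check.names = FALSE)
  tab4$mystery <- 1
  unk <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab4, unk, row.names = FALSE)
  expect_warning(load_survey(unk, cb), "unknown survey columns: mystery")
})

test_that("missingness policies: refuse, drop respondent, or impute zero", {
  cb <- tiny_codebook()
  ds <- tiny_survey(cb)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(ds, f)
  tab <- read.csv(f, check.names = FALSE, colClasses = "character")
  tab$s_b2[3] <- ""
  g <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, g, row.names = FALSE)
  expect_error(load_survey(g, cb), "missing cells.*row.* 3")
  expect_message(ds_drop <- load_survey(g, cb, missing = "drop"),
                 "dropping 1 respondent")
  expect_identical(ds_drop$respondent_ids, c("R1", "R2", "R4"))
  ds_imp <- load_survey(g, cb, missing = "impute_zero")
  expect_identical(unname(ds_imp$symptoms[3, "s_b2"]), 0L)
  expect_identical(length(ds_imp$respondent_ids), 4L)
})

test_that("write_results emits stable CSVs and a manifest", {
  prev <- data.frame(item = c("a", "b"), n_positive = c(3L, 1L),
                     prevalence = c(0.75, 0.25))
  d1 <- withr::local_tempdir()
  m <- write_results(list(prevalence = prev), d1, config_hash = "abc")
  expect_identical(m$files[[1]]$name, "prevalence.csv")
  expect_identical(m$files[[1]]$rows, 2L)
  expect_identical(m$config_hash, "abc")
  got <- read.csv(file.path(d1, "prevalence.csv"))
  expect_identical(names(got), c("item", "n_positive", "prevalence"))
  # Empty table set -> manifest with zero entries.
  d2 <- withr::local_tempdir()
  m0 <- write_results(setNames(list(), character()), d2)
  expect_identical(m0$n_tables, 0L)
  # Rerun is byte-identical.
  d3 <- withr::local_tempdir()
  write_results(list(prevalence = prev), d3, config_hash = "abc")
  expect_identical(readBin(file.path(d1, "prevalence.csv"), "raw", 1e5),
                   readBin(file.path(d3, "prevalence.csv"), "raw", 1e5))
})
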