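test_that("feature tables round-trip through write/read", {
  lib <- synth_library(4)
  sim <- simulate_feature_tables(lib, n_products = 4, n_replicates = 2,
                                 seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$neg, path)
  back <- read_feature_table(path, polarity = "-")
  expect_equal(back$mz, sim$neg$mz, tolerance = 1e-9)
  expect_equal(back$rt, sim$neg$rt, tolerance = 1e-9)
  expect_equal(intensity_matrix(back), intensity_matrix(sim$neg),
               tolerance = 1e-6)
})

test_that("feature-table validation rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tmz\trt\tintensity_a",
               "f1\t100.5\t10\t5", "f2\t-3\t10\t5"), path)
  expect_error(read_feature_table(path), "positive")
  writeLines(c("feature_id\tmz\tintensity_a", "f1\t100.5\t5"), path)
  expect_error(read_feature_table(path), "missing column")
  writeLines(c("feature_id\tmz\trt\tintensity_a",
               "f1\t100.5\t10\tlots"), path)
  expect_error(read_feature_table(path), "non-numeric")
  writeLines(c("feature_id\tmz\trt\tintensity_a",
               "f1\t100.5\t10\t5", "f1\t101.5\t10\t5"), path)
  expect_error(read_feature_table(path), "duplicate")
})

test_that("MGF spectra parse, normalize, sort and round-trip", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=539.1770", "CHARGE=1-",
               "RTINSECONDS=381", "377.1243 20", "153.0557 80",
               "307.0823 40", "END IONS"), path)
  sp <- read_mgf(path)
  expect_length(sp, 1L)
  s <- sp[[1]]
  expect_equal(s$precursor_mz, 539.1770)
  expect_identical(s$polarity, "-")
  expect_false(is.unsorted(s$peaks[, "mz"]))
  expect_equal(max(s$peaks[, "intensity"]), 1)
  out <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, out)
  again <- read_mgf(out)[[1]]
  expect_equal(again$peaks, s$peaks, tolerance = 1e-6)
  expect_equal(again$precursor_mz, s$precursor_mz, tolerance = 1e-6)
})

test_that("MGF edge cases: empty block warns, missing precursor errors", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=300.1", "END IONS"), path)
  expect_warning(sp <- read_mgf(path), "empty peak list")
  expect_identical(nrow(sp[[1]]$peaks), 0L)
  writeLines(c("BEGIN IONS", "100.0 5", "END IONS"), path)
  expect_error(read_mgf(path), "PEPMASS")
})

test_that("annotation fixture has the printed structure", {
  tab <- load_table1_fixture()
  expect_identical(nrow(tab), 202L)
  counts <- table(tab$level)
  expect_identical(as.integer(counts[c("I", "II", "III")]),
                   c(15L, 66L, 121L))
  expect_identical(sum(grepl("derivative", tab$name)), 21L)
  expect_identical(tab$formula[tab$compound_id == "C050"], "C8H10O3")
  # every formula parses; every ion entry is parseable or explicitly flagged
  for (i in seq_len(nrow(tab))) {
    expect_no_error(parse_formula(tab$formula[i]))
    ions <- parse_ion_entries(tab$ions[i])
    expect_true(all(ions$mz > 0))
    expect_true(all(ions$kind %in% c("adduct", "fragment", "other")))
  }
})

test_that("concentration ranges parse with the censoring conventions", {
  parsed <- parse_conc_range(c("74.83–88.2", "ND", "<LOQ", "LOQ–0.14",
                               "ND–<LOQ", "ND–0.03", "0–0.01"))
  expect_equal(parsed$lo, c(74.83, 0, 0, 0, 0, 0, 0))
  expect_equal(parsed$hi, c(88.2, 0, 0, 0.14, 0, 0.03, 0.01))
  expect_identical(parsed$censoring,
                   c("measured", "not_detected", "below_loq", "mixed",
                     "mixed", "mixed", "measured"))
  expect_error(parse_conc_range("banana"), "unparseable")
})

test_that("concentration and product fixtures carry the printed values", {
  t3 <- load_table3_fixture()
  expect_identical(nrow(t3), 26L * 14L)
  h <- t3[t3$compound == "Hydroxytyrosol" & t3$product == "H", ]
  expect_equal(c(h$lo, h$hi), c(74.83, 88.2))
  vk <- t3[t3$compound == "Verbascoside" & t3$product == "K", ]
  expect_identical(vk$censoring, "not_detected")
  expect_equal(c(vk$lo, vk$hi), c(0, 0))
  t4 <- load_table4_fixture()
  expect_identical(nrow(t4), 14L)
  expect_equal(t4$daily_dose_g[t4$product == "J"], 72.8)
  expect_equal(t4$daily_dose_g[t4$product == "H"], 0.025)
  targeted <- load_targeted_compounds()
  expect_identical(nrow(targeted), 26L)
  expect_identical(
    targeted$surrogate_standard[targeted$compound == "Hydroxytyrosol glucoside (I)"],
    "Hydroxytyrosol")
  expect_identical(targeted$surrogate_standard[targeted$compound == "DEDA"],
                   "Oleuropein")
})

test_that("fixture integrity failures are detected", {
  # corrupting a copy and pointing the loader at it must raise the
  # dedicated condition class
  tmp <- withr::local_tempdir()
  dir.create(file.path(tmp, "extdata"))
  src <- system.file("extdata", "table4_products.tsv", package = "olivemet")
  txt <- readLines(src)
  txt[2] <- sub("buds", "stems", txt[2])
  writeLines(txt, file.path(tmp, "extdata", "table4_products.tsv"))
  sum <- unname(tools::md5sum(file.path(tmp, "extdata",
                                        "table4_products.tsv")))
  expect_error(
    stop(olivemet:::fixture_integrity_error("table4_products.tsv", sum)),
    class = "fixture_integrity_error")
  expect_false(identical(
    sum, unname(olivemet:::FIXTURE_CHECKSUMS[["table4_products.tsv"]])))
})
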