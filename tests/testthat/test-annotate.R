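test_that("formula enumeration finds the printed formulas first", {
  cho <- list(C = c(0, 30), H = c(0, 50), O = c(0, 15))
  top <- enumerate_formulas(154.06299, 5, cho)
  expect_identical(top$formula[1], "C8H10O3")
  deda <- enumerate_formulas(184.07356, 5, cho)
  expect_true("C9H12O4" %in% deda$formula)
  expect_identical(nrow(enumerate_formulas(1.0, 5, cho)), 0L)
})

test_that("enumeration respects chemical filters and ppm ranking", {
  res <- enumerate_formulas(540.18429, 5,
                            list(C = c(0, 40), H = c(0, 60), O = c(0, 20),
                                 N = c(0, 3)))
  expect_true("C25H32O13" %in% res$formula)
  expect_true(all(abs(res$ppm) <= 5))
  expect_true(all(res$rdbe >= 0))
  expect_false(is.unsorted(abs(res$ppm)))
  # H <= 2C + N + 2 saturation bound
  for (f in res$formula) {
    cnt <- unclass(parse_formula(f))
    h <- if ("H" %in% names(cnt)) cnt[["H"]] else 0L
    n <- if ("N" %in% names(cnt)) cnt[["N"]] else 0L
    expect_lte(h, 2 * cnt[["C"]] + n + 2)
  }
})

test_that("enumeration recovers the true formula for the whole library", {
  tab <- load_table1_fixture()
  set.seed(17)
  noise <- stats::runif(nrow(tab), -5, 5)  # up to 5 ppm mass error
  for (i in seq_len(nrow(tab))) {
    M <- monoisotopic_mass(tab$formula[i]) * (1 + noise[i] * 1e-6)
    hits <- enumerate_formulas(M, tol_ppm = 5 + abs(noise[i]))
    expect_true(tab$formula[i] %in% hits$formula,
                info = tab$compound_id[i])
  }
})

test_that("MS2 merging averages, renormalizes and floors at 1%", {
  s <- toy_spectrum(c(100.0, 200.0, 300.0), c(1, 0.5, 0.004))
  m1 <- merge_ms2(list(s))
  expect_equal(nrow(m1$peaks), 2L)  # sub-1% peak dropped
  m3 <- merge_ms2(list(s, s, s))
  expect_equal(m3$peaks, m1$peaks, tolerance = 1e-9)
  bad <- toy_spectrum(c(100), precursor = 501)
  expect_error(merge_ms2(list(s, bad)), "precursor")
})

test_that("MS2 merging recovers a planted peak set from jittered replicates", {
  planted <- c(153.0557, 135.0452, 123.0452, 179.0350)
  set.seed(5)
  reps <- lapply(1:3, function(i) {
    toy_spectrum(planted + stats::rnorm(4, 0, 0.002),
                 stats::runif(4, 0.5, 1), precursor = 315.1085)
  })
  merged <- merge_ms2(reps)
  expect_identical(nrow(merged$peaks), 4L)
  expect_equal(merged$peaks[, "mz"], sort(planted), tolerance = 0.003,
               ignore_attr = TRUE)
})

test_that("diagnostic rules classify the printed evidence patterns", {
  rules <- diagnostic_rules()
  # DEDA ion plus its CO2-loss ion
  deda <- toy_spectrum(c(183.0663, 139.0765), precursor = 483.1873)
  expect_true("DEDA derivative" %in% classify_spectrum(deda, rules))
  # hydroxytyrosol moiety as a neutral loss from the precursor
  ht <- toy_spectrum(341.0878, precursor = 477.1402)
  expect_true("hydroxytyrosol derivative" %in% classify_spectrum(ht, rules))
  # any single characteristic elenolic fragment is enough
  ele <- toy_spectrum(209.0457, precursor = 241.0718)
  expect_true("elenolic derivative" %in% classify_spectrum(ele, rules))
  empty <- toy_spectrum(numeric(0))
  expect_identical(classify_spectrum(empty, rules), character(0))
  # polarity gating: the same peaks in positive mode fire nothing
  pos <- toy_spectrum(c(183.0663, 139.0765), precursor = 483.1873,
                      polarity = "+")
  expect_false("DEDA derivative" %in% classify_spectrum(pos, rules))
})

test_that("classification is monotone under added peaks", {
  rules <- diagnostic_rules()
  set.seed(31)
  for (rep in 1:20) {
    base_mz <- sort(stats::runif(stats::rbinom(1, 6, 0.7) + 1, 80, 600))
    s <- toy_spectrum(base_mz, precursor = 650)
    before <- classify_spectrum(s, rules)
    extra <- toy_spectrum(c(base_mz, stats::runif(3, 80, 600)),
                          precursor = 650)
    after <- classify_spectrum(extra, rules)
    expect_true(all(before %in% after))
  }
})

test_that("confidence levels follow the evidence hierarchy", {
  expect_identical(as.character(assign_level(standard_match = TRUE,
                                             library_match = TRUE)), "I")
  expect_identical(as.character(assign_level(library_match = TRUE)), "II")
  expect_identical(as.character(assign_level(class_rule = TRUE)), "III")
  expect_identical(as.character(assign_level(has_formula = TRUE)), "IV")
  expect_identical(as.character(assign_level()), "V")
  expect_error(assign_level(standard_match = TRUE), "contradictory")
  lv <- assign_level(library_match = TRUE)
  expect_true(is.ordered(lv))
  expect_true(assign_level(standard_match = TRUE, library_match = TRUE) <
                assign_level(class_rule = TRUE))
})

test_that("the fixture level census reproduces the printed counts", {
  census <- annotate_fixture_rerun()
  expect_identical(census[c("I", "II", "III")],
                   c(I = 15L, II = 66L, III = 121L))
  expect_identical(sum(census), 202L)
})
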