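test_that("the hydroxytyrosol pseudo-spectrum is fully deciphered", {
  # printed negative-mode ion cluster of hydroxytyrosol (M = 154.0630)
  mzs <- c(153.0558, 154.0592, 307.1187, 189.0325, 199.0613, 123.0455)
  ints <- outer(c(100, 9, 20, 10, 8, 15), c(1, 2, 3))
  g <- group_features(toy_features(mzs, 170, ints))[[1]]
  h <- infer_roles(g, tol_ppm = 5)
  expect_equal(h$M, 154.0630, tolerance = 1e-4)
  expect_identical(h$explained_count, 6L)
  a <- h$assignments
  expect_identical(a$role[a$mz == 153.0558], "molecular_ion")
  expect_identical(a$detail[a$mz == 154.0592], "13C[M-H]-")
  expect_identical(a$detail[a$mz == 307.1187], "[2M-H]-")
  expect_identical(a$detail[a$mz == 189.0325], "[M+Cl]-")
  expect_identical(a$detail[a$mz == 199.0613], "[M-H+HCOOH]-")
  expect_identical(a$role[a$mz == 123.0455], "in_source_fragment")
  expect_identical(a$detail[a$mz == 123.0455], "CH2O")
})

test_that("a singleton inverts the default adduct and is flagged", {
  g <- group_features(toy_features(539.1770, 381,
                                   matrix(c(5, 6, 7), nrow = 1)))[[1]]
  h <- infer_roles(g)
  expect_equal(h$M, 540.1843, tolerance = 1e-4)
  expect_identical(h$assignments$role, "molecular_ion")
  expect_true(h$flagged)
})

test_that("unrelated masses stay unexplained", {
  ints <- rbind(c(10, 20, 30), c(11, 22, 33))
  g <- group_features(toy_features(c(400.123, 457.777), 100, ints))[[1]]
  h <- infer_roles(g)
  expect_identical(h$explained_count, 1L)
  expect_identical(sum(h$assignments$role == "unexplained"), 1L)
})

test_that("roles round-trip through the adduct calculus", {
  lib <- synth_library(8, seed = 7)
  sim <- simulate_feature_tables(lib, seed = 42)
  reg <- adduct_registry()
  for (pol in c("neg", "pos")) {
    for (g in group_features(sim[[pol]])) {
      h <- infer_roles(g)
      a <- h$assignments[h$assignments$role != "unexplained", ]
      for (i in seq_len(nrow(a))) {
        theo <- if (a$role[i] == "in_source_fragment") {
          base <- if (g$polarity == "-") "[M-H]-" else "[M+H]+"
          loss <- neutral_losses()
          olivemet:::mz_for_neutral_mass(h$M, olivemet:::get_adduct(base)) -
            loss$mass[loss$name == a$detail[i]]
        } else {
          olivemet:::mz_for_neutral_mass(h$M,
                                         reg[reg$name == a$detail[i], ])
        }
        expect_lt(abs(ppm_error(a$mz[i], theo)), 5)
      }
    }
  }
})

test_that("role recovery is 100% over >=100 simulated groups", {
  lib_all <- load_table1_fixture()
  set.seed(123)
  lib <- lib_all[sample(nrow(lib_all), 60), c("name", "formula", "rt_s")]
  # spread retention times so the planted partition is unambiguous
  lib$rt_s <- seq(40, 40 + 25 * (nrow(lib) - 1), by = 25)
  sim <- simulate_feature_tables(lib, n_products = 8, n_replicates = 3,
                                 ppm_sigma = 1, seed = 99)
  n_groups <- 0L; n_roles <- 0L; n_correct <- 0L
  for (pol in c("neg", "pos")) {
    for (g in group_features(sim[[pol]])) {
      h <- infer_roles(g, tol_ppm = 5)
      tr <- sim$truth[match(h$assignments$feature_id,
                            sim$truth$feature_id), ]
      pred <- predicted_roles(h$assignments)
      n_groups <- n_groups + 1L
      n_roles <- n_roles + nrow(tr)
      n_correct <- n_correct + sum(pred == tr$role)
    }
  }
  expect_gte(n_groups, 100L)
  expect_identical(n_correct, n_roles)
})

test_that("isotope roles require a more intense monoisotopic partner", {
  lib <- synth_library(8, seed = 7)
  sim <- simulate_feature_tables(lib, seed = 42)
  for (g in group_features(sim$neg)) {
    h <- infer_roles(g)
    iso <- h$assignments[h$assignments$role == "isotope", ]
    peak <- apply(intensity_matrix(g$members), 1, max)
    for (i in seq_len(nrow(iso))) {
      mono_mz <- iso$mz[i] - iso$isotope_k[i] * 1.003355
      partner <- which(abs(ppm_error(g$members$mz, mono_mz)) <= 5)
      expect_true(length(partner) > 0)
      expect_gt(max(peak[partner]),
                peak[[match(iso$feature_id[i], g$members$feature_id)]])
    }
  }
})

test_that("cross-polarity reconciliation merges agreeing hypotheses only", {
  ints <- matrix(c(50, 60, 70), nrow = 1)
  neg <- infer_roles(group_features(toy_features(539.1770, 381, ints))[[1]])
  # oleuropein in positive mode: protonated and ammoniated species
  pints <- rbind(c(80, 90, 100), c(40, 45, 50))
  pos <- infer_roles(group_features(
    toy_features(c(541.1915, 558.2181), 381, pints, polarity = "+"))[[1]])
  expect_equal(pos$M, 540.1843, tolerance = 1e-3)
  merged <- reconcile_polarities(neg, pos)
  expect_s3_class(merged, "neutral_hypothesis")
  expect_equal(merged$M, 540.1843, tolerance = 1e-3)
  expect_setequal(merged$polarity_support, c("-", "+"))

  off <- pos; off$M <- pos$M * (1 + 10e-6)   # 10 ppm away
  expect_null(reconcile_polarities(neg, off))
  late <- pos; late$rt_centroid <- neg$rt_centroid + 30
  expect_null(reconcile_polarities(neg, late))
  expect_error(reconcile_polarities(neg, neg), "opposite")
})
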