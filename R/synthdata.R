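# Synthetic-data generators with the statistical structure the pipeline
# assumes: co-eluting adduct/isotope/fragment ion clusters with ppm mass
# noise and correlated intensities, MS2 spectra drawn from the class rules,
# and calibration series.

#' Simulate per-sample feature tables with planted ion structure
#'
#' For every compound of the supplied library, a cluster of co-eluting ions
#' is generated through the adduct registry: the (de)protonated ion is
#' always present and most intense; 13C isotopologues, dimers, chloride /
#' formate / ammonium / sodium adducts and a water-loss in-source fragment
#' are included with realistic probabilities and relative abundances.
#' Theoretical m/z values receive Gaussian relative mass noise (default
#' sigma 1 ppm, well inside the instrument's 5 ppm accuracy), retention
#' times a shared per-compound jitter (default sigma 1 s) plus a small
#' per-ion apex shift (sigma 0.2 s). Abundances are log-normal with
#' product-level means and share one per-compound profile across all ions,
#' giving the intensity correlation structure the grouping step assumes.
#'
#' @param library Data frame with columns `name`, `formula`, `rt_s`
#'   (e.g. rows of [load_table1_fixture()]).
#' @param n_products,n_replicates Sample design (defaults 14 products x 3
#'   replicates, the study layout).
#' @param ppm_sigma Relative mass-noise sigma in ppm (default 1).
#' @param rt_sigma_s Per-compound RT jitter sigma in seconds (default 1).
#' @param seed Random seed; fixed seed gives identical output.
#' @return A list with `neg` and `pos` `feature_table`s and `truth`, a data
#'   frame mapping every generated feature to its compound, role (adduct
#'   name or `frag:<loss>`), and neutral mass.
#' @export
simulate_feature_tables <- function(library, n_products = 14,
                                    n_replicates = 3, ppm_sigma = 1,
                                    rt_sigma_s = 1, seed = 1) {
  stopifnot(nrow(library) >= 1L, ppm_sigma >= 0, rt_sigma_s >= 0)
  set.seed(seed)
  samples <- paste0("S", rep(seq_len(n_products), each = n_replicates),
                    "_", rep(seq_len(n_replicates), n_products))
  n_samp <- length(samples)

  neg_optional <- c("13C[M-H]-" = 0.7, "[2M-H]-" = 0.5, "[M+Cl]-" = 0.4,
                    "[M-H+HCOOH]-" = 0.4)
  pos_optional <- c("13C[M+H]+" = 0.7, "[M+NH4]+" = 0.6, "[M+Na]+" = 0.4)

  feats <- list(); truth <- list(); counter <- 0L
  emit <- function(polarity, compound, role, M, mz_theo, rt, intensities) {
    counter <<- counter + 1L
    id <- sprintf("%s%04d", if (polarity == "-") "FN" else "FP", counter)
    mz <- mz_theo * (1 + stats::rnorm(1, 0, ppm_sigma * 1e-6))
    row <- c(list(feature_id = id, mz = mz, rt = rt, polarity = polarity),
             as.list(stats::setNames(intensities,
                                     paste0("intensity_", samples))))
    feats[[counter]] <<- as.data.frame(row, stringsAsFactors = FALSE,
                                       check.names = FALSE)
    truth[[counter]] <<- data.frame(feature_id = id, polarity = polarity,
                                    compound = compound, role = role,
                                    neutral_mass = M,
                                    stringsAsFactors = FALSE)
  }

  for (k in seq_len(nrow(library))) {
    f <- parse_formula(library$formula[k])
    M <- monoisotopic_mass(f)
    nC <- if ("C" %in% names(f)) unclass(f)[["C"]] else 0L
    rt_k <- library$rt_s[k] + stats::rnorm(1, 0, rt_sigma_s)
    # per-compound abundance profile shared (up to tiny noise) by all ions
    prod_mean <- stats::rnorm(n_products, log(1e6), 1)
    profile <- exp(rep(prod_mean, each = n_replicates) +
                     stats::rnorm(n_samp, 0, 0.15))
    for (pol in c("-", "+")) {
      base <- if (pol == "-") "[M-H]-" else "[M+H]+"
      optional <- if (pol == "-") neg_optional else pos_optional
      ions <- c(stats::setNames(1, base),
                vapply(names(optional), function(a) {
                  if (stats::runif(1) < optional[[a]]) {
                    if (startsWith(a, "13C")) 0.011 * nC
                    else stats::runif(1, 0.1, 0.5)
                  } else NA_real_
                }, numeric(1)))
      ions <- ions[!is.na(ions)]
      for (a in names(ions)) {
        emit(pol, library$name[k], a, M, mz_for_adduct(f, a),
             rt_k + stats::rnorm(1, 0, 0.2),
             profile * ions[[a]] * exp(stats::rnorm(n_samp, 0, 0.02)))
      }
      # a water-loss in-source fragment of the base ion
      if (stats::runif(1) < 0.4 && M > 100) {
        lmass <- neutral_losses()$mass[neutral_losses()$name == "H2O"]
        emit(pol, library$name[k], "frag:H2O", M,
             mz_for_adduct(f, base) - lmass,
             rt_k + stats::rnorm(1, 0, 0.2),
             profile * stats::runif(1, 0.1, 0.4) *
               exp(stats::rnorm(n_samp, 0, 0.02)))
      }
    }
  }
  all_feats <- do.call(rbind, feats)
  truth <- do.call(rbind, truth)
  split_pol <- function(p) {
    df <- all_feats[all_feats$polarity == p, , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("feature_table", "data.frame")
    df
  }
  list(neg = split_pol("-"), pos = split_pol("+"), truth = truth)
}

#' Simulate MS2 spectra from the diagnostic class rules
#'
#' Each generated spectrum carries the diagnostic fragments (and
#' neutral-loss ions) of one class, optionally jittered, plus decoy peaks
#' drawn away from every diagnostic value, so classifier accuracy is
#' directly measurable. Decoy-only spectra (true label `"none"`) can be
#' added as negative controls.
#'
#' @param rules Rule set (default [diagnostic_rules()]).
#' @param n_per_class Spectra per rule (default 5).
#' @param noise_da Gaussian m/z jitter sigma in Da (default 0).
#' @param n_decoys Decoy peaks per spectrum (default 5).
#' @param n_decoy_only Additional spectra containing only decoys.
#' @param seed Random seed.
#' @return A list with `spectra` (list of `ms2_spectrum`) and `labels`
#'   (character; `"none"` for decoy-only spectra).
#' @export
simulate_ms2 <- function(rules = diagnostic_rules(), n_per_class = 5,
                         noise_da = 0, n_decoys = 5, n_decoy_only = 0,
                         seed = 1) {
  set.seed(seed)
  losses <- neutral_losses()
  forbidden <- unique(unlist(lapply(rules, `[[`, "required_any")))
  draw_decoys <- function(n, precursor) {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(1, 80, precursor - 5)
      clash <- any(abs(cand - forbidden) < 0.02) ||
        any(abs((precursor - cand) - losses$mass) < 0.02)
      if (!clash) out <- c(out, cand)
    }
    out
  }
  spectra <- list(); labels <- character(0)
  for (r in rules) {
    for (i in seq_len(n_per_class)) {
      precursor <- stats::runif(1, 450, 650)
      mzs <- r$required_any[r$required_any < precursor - 10]
      for (lname in r$required_losses) {
        mzs <- c(mzs, precursor - losses$mass[losses$name == lname])
      }
      mzs <- mzs + stats::rnorm(length(mzs), 0, noise_da)
      ints <- stats::runif(length(mzs), 0.3, 1)
      dec <- draw_decoys(n_decoys, precursor)
      peaks <- cbind(mz = c(mzs, dec),
                     intensity = c(ints, stats::runif(n_decoys, 0.05, 0.8)))
      peaks[, "intensity"] <- peaks[, "intensity"] /
        max(peaks[, "intensity"])
      peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
      spectra[[length(spectra) + 1L]] <-
        new_ms2_spectrum(precursor, r$polarity, stats::runif(1, 60, 600),
                         peaks)
      labels <- c(labels, r$class_name)
    }
  }
  for (i in seq_len(n_decoy_only)) {
    precursor <- stats::runif(1, 450, 650)
    dec <- draw_decoys(n_decoys, precursor)
    peaks <- cbind(mz = sort(dec), intensity = stats::runif(n_decoys, 0.05, 1))
    peaks[, "intensity"] <- peaks[, "intensity"] / max(peaks[, "intensity"])
    spectra[[length(spectra) + 1L]] <-
      new_ms2_spectrum(precursor, sample(c("-", "+"), 1),
                       stats::runif(1, 60, 600), peaks)
    labels <- c(labels, "none")
  }
  list(spectra = spectra, labels = labels)
}

#' Simulate a calibration series
#'
#' Linear responses `intercept + slope * concentration` with multiplicative
#' Gaussian noise, mirroring the heteroscedasticity of detector responses.
#'
#' @param slope,intercept Line parameters (e.g. from
#'   [load_table2_fixture()]).
#' @param concentrations Concentration grid in mg/L (nonempty).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed Random seed.
#' @return A data frame with columns `concentration` and `response`.
#' @export
simulate_calibration <- function(slope, intercept = 0, concentrations,
                                 noise_cv = 0, seed = 1) {
  if (!length(concentrations)) {
    stop("empty concentration grid", call. = FALSE)
  }
  set.seed(seed)
  response <- (intercept + slope * concentrations) *
    (1 + stats::rnorm(length(concentrations), 0, noise_cv))
  data.frame(concentration = concentrations, response = response)
}
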