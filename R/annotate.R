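# Formula enumeration, MS2 merging, diagnostic-fragment class rules, and
# confidence-level assignment.

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Exhaustively enumerates CHNOPS formulas inside `element_bounds` whose
#' monoisotopic mass is within `tol_ppm` of `M`, subject to chemical
#' plausibility filters: ring-and-double-bond equivalents (RDBE) >= 0 and
#' H <= 2C + N + 2. Candidates are ranked by |ppm|.
#'
#' @param M Neutral monoisotopic mass in Da, positive.
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @param element_bounds Named list of `c(min, max)` count bounds per
#'   element; allowed names are C, H, N, O, S, P. Elements absent from the
#'   list are fixed at zero. The default covers typical plant secondary
#'   metabolites up to ~800 Da.
#' @return A data frame with columns `formula`, `mass`, `ppm` and `rdbe`,
#'   ordered by |ppm|; empty (zero rows) when nothing fits the bounds.
#' @examples
#' enumerate_formulas(154.06299, element_bounds =
#'   list(C = c(0, 20), H = c(0, 40), O = c(0, 10)))
#' @export
enumerate_formulas <- function(M, tol_ppm = 5,
                               element_bounds = list(C = c(0, 50),
                                                     H = c(0, 80),
                                                     N = c(0, 5),
                                                     O = c(0, 25),
                                                     S = c(0, 2),
                                                     P = c(0, 2))) {
  stopifnot(is.numeric(M), length(M) == 1L, M > 0,
            length(element_bounds) >= 1L)
  allowed <- c("C", "H", "N", "O", "S", "P")
  if (!all(names(element_bounds) %in% allowed)) {
    stop("element_bounds may only contain ", paste(allowed, collapse = ","),
         call. = FALSE)
  }
  b <- function(el) {
    if (el %in% names(element_bounds)) {
      bounds <- element_bounds[[el]]
      # cap by the mass budget so the candidate grid stays small
      bounds[2] <- min(bounds[2],
                       floor((M + 1) / ATOMIC_MASSES[[el]]))
      if (bounds[2] < bounds[1]) return(integer(0))
      bounds[1]:bounds[2]
    } else 0L
  }
  tol_da <- M * tol_ppm * 1e-6
  mH <- ATOMIC_MASSES[["H"]]
  grid <- expand.grid(C = b("C"), N = b("N"), O = b("O"), S = b("S"),
                      P = b("P"), KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      ppm = numeric(0), rdbe = numeric(0)))
  }
  rest <- grid$C * 12 + grid$N * ATOMIC_MASSES[["N"]] +
    grid$O * ATOMIC_MASSES[["O"]] + grid$S * ATOMIC_MASSES[["S"]] +
    grid$P * ATOMIC_MASSES[["P"]]
  h <- round((M - rest) / mH)
  hb <- if ("H" %in% names(element_bounds)) element_bounds[["H"]]
        else c(0L, 0L)
  mass <- rest + h * mH
  dev <- 1e6 * (mass - M) / M
  rdbe <- grid$C - h / 2 + grid$N / 2 + 1
  keep <- h >= hb[1] & h <= hb[2] & h <= 2 * grid$C + grid$N + 2 &
    rdbe >= 0 & abs(dev) <= tol_ppm
  if (!any(keep)) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      ppm = numeric(0), rdbe = numeric(0)))
  }
  grid <- grid[keep, , drop = FALSE]
  grid$H <- h[keep]
  formula <- vapply(seq_len(nrow(grid)), function(i) {
    counts <- c(C = grid$C[i], H = grid$H[i], N = grid$N[i], O = grid$O[i],
                S = grid$S[i], P = grid$P[i])
    counts <- counts[counts > 0]
    f <- structure(as.integer(counts), names = names(counts))
    f <- f[hill_order(names(f))]
    class(f) <- "molecular_formula"
    format(f)
  }, character(1))
  res <- data.frame(formula = formula, mass = mass[keep], ppm = dev[keep],
                    rdbe = rdbe[keep], stringsAsFactors = FALSE)
  res <- res[order(abs(res$ppm)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge replicate MS2 spectra into a consensus spectrum
#'
#' Peaks from up to three (or more) spectra of the same precursor are
#' aligned within 0.005 Da, their relative intensities averaged over all
#' input spectra (a peak absent from a spectrum contributes zero), the
#' result renormalized to a base peak of 1, and fragments below
#' `min_rel_int` discarded.
#'
#' @param spectra List of `ms2_spectrum` objects with matching precursors.
#' @param min_rel_int Relative-intensity floor (default 0.01, i.e. the
#'   ">1 percent" rule).
#' @param align_tol Peak-alignment tolerance in Da (default 0.005).
#' @param precursor_tol Maximum precursor spread in Da (default 0.01).
#' @return A single consensus `ms2_spectrum`.
#' @export
merge_ms2 <- function(spectra, min_rel_int = 0.01, align_tol = 0.005,
                      precursor_tol = 0.01) {
  stopifnot(length(spectra) >= 1L)
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  if (diff(range(prec)) > precursor_tol) {
    stop("precursor m/z mismatch across spectra", call. = FALSE)
  }
  pol <- spectra[[1]]$polarity
  all_peaks <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    p <- spectra[[i]]$peaks
    if (!nrow(p)) return(NULL)
    cbind(p, spectrum = i)
  }))
  if (is.null(all_peaks) || !nrow(all_peaks)) {
    return(new_ms2_spectrum(mean(prec), pol, spectra[[1]]$rt,
                            cbind(mz = numeric(0), intensity = numeric(0))))
  }
  ord <- order(all_peaks[, "mz"])
  all_peaks <- all_peaks[ord, , drop = FALSE]
  # single-linkage clusters: break where consecutive gap exceeds align_tol
  gaps <- diff(all_peaks[, "mz"]) > align_tol
  cluster <- cumsum(c(TRUE, gaps))
  mz <- tapply(all_peaks[, "mz"], cluster, mean)
  intensity <- tapply(all_peaks[, "intensity"], cluster, sum) /
    length(spectra)
  intensity <- intensity / max(intensity)
  keep <- intensity >= min_rel_int
  peaks <- cbind(mz = as.numeric(mz[keep]),
                 intensity = as.numeric(intensity[keep]))
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  new_ms2_spectrum(mean(prec), pol, spectra[[1]]$rt, peaks)
}

#' Diagnostic-fragment rules for olive compound classes
#'
#' The hard-coded rule library for the compound families that dominate
#' olive extracts. A rule lists characteristic fragment m/z values
#' (`required_any`) and/or neutral losses from the precursor
#' (`required_losses`); it fires when at least `min_hits` of them are
#' observed. Fragment values are matched at the printing precision of the
#' reference tables (0.005 Da).
#'
#' Families: hydroxytyrosol (fragments -153.0557/-135.0452/-123.0452,
#' +155.0703/+137.0597, or a 136.0524 Da hydroxytyrosol neutral loss),
#' tyrosol/ligstroside (-361.1293/-291.0874/-259.0976), oleuropein
#' (-377.1243/-345.0980/-307.0823/-275.0561/-275.0925), elenolic acid
#' (-209.0457/-165.0561/-121.0300/-95.0509), DEDA (the decarboxymethyl
#' elenolic acid dialdehyde ion -183.0663/+185.0808 plus a CO2 or water
#' loss ion) and oleoside/secologanoside
#' (-345.1191/-227.0561/-209.0455/-183.0663).
#'
#' @return A list of `diagnostic_rule` objects (fields `class_name`,
#'   `polarity`, `required_any`, `required_losses`, `min_hits`).
#' @export
diagnostic_rules <- function() {
  rule <- function(class_name, polarity, required_any = numeric(0),
                   required_losses = character(0), min_hits = 1L) {
    structure(list(class_name = class_name, polarity = polarity,
                   required_any = required_any,
                   required_losses = required_losses,
                   min_hits = as.integer(min_hits)),
              class = "diagnostic_rule")
  }
  list(
    rule("hydroxytyrosol derivative", "-",
         required_any = c(153.0557, 135.0452, 123.0452),
         required_losses = "hydroxytyrosol"),
    rule("hydroxytyrosol derivative", "+",
         required_any = c(155.0703, 137.0597),
         required_losses = "hydroxytyrosol"),
    rule("tyrosol/ligstroside derivative", "-",
         required_any = c(361.1293, 291.0874, 259.0976)),
    rule("oleuropein derivative", "-",
         required_any = c(377.1243, 345.0980, 307.0823, 275.0561, 275.0925)),
    rule("elenolic derivative", "-",
         required_any = c(209.0457, 165.0561, 121.0300, 95.0509)),
    rule("DEDA derivative", "-",
         required_any = c(183.0663, 165.0557, 139.0765), min_hits = 2L),
    rule("DEDA derivative", "+",
         required_any = c(185.0808, 167.0703), min_hits = 2L),
    rule("oleoside/secologanoside derivative", "-",
         required_any = c(345.1191, 227.0561, 209.0455, 183.0663),
         min_hits = 2L)
  )
}

#' Classify an MS2 spectrum by diagnostic-fragment rules
#'
#' A rule fires when at least `min_hits` of its evidence items are present:
#' a fragment peak within `tol` of a required m/z, or a peak whose
#' precursor-minus-fragment difference is within `tol` of a required
#' neutral-loss mass. Classification is multi-label: all firing classes are
#' returned. Adding peaks to a spectrum can only add classes, never remove
#' them.
#'
#' @param s An `ms2_spectrum`.
#' @param rules Rule set, default [diagnostic_rules()].
#' @param tol Absolute fragment tolerance in Da (default 0.005, the
#'   printing precision of the diagnostic values).
#' @return Character vector of class names (possibly empty).
#' @export
classify_spectrum <- function(s, rules = diagnostic_rules(), tol = 0.005) {
  stopifnot(inherits(s, "ms2_spectrum"), length(rules) >= 1L)
  if (!nrow(s$peaks)) return(character(0))
  mzs <- s$peaks[, "mz"]
  losses <- neutral_losses()
  hits_for <- function(rule) {
    n <- 0L
    for (frag in rule$required_any) {
      if (any(abs(mzs - frag) <= tol)) n <- n + 1L
    }
    for (lname in rule$required_losses) {
      lmass <- losses$mass[match(lname, losses$name)]
      if (any(abs((s$precursor_mz - mzs) - lmass) <= tol)) n <- n + 1L
    }
    n
  }
  fired <- vapply(rules, function(r) {
    r$polarity == s$polarity && hits_for(r) >= r$min_hits
  }, logical(1))
  unique(vapply(rules[fired], function(r) r$class_name, character(1)))
}

LEVELS <- c("I", "II", "III", "IV", "V")

#' Assign a Metabolomics Standards Initiative confidence level
#'
#' Level I requires an analytical-standard match (retention time and MS2);
#' level II an MS2 match against a spectral library or the literature;
#' level III a class-level call from diagnostic rules or in-silico
#' fragmentation; level IV a molecular formula only; level V an accurate
#' mass only.
#'
#' @param standard_match RT + MS2 agreement with an authentic standard.
#' @param library_match MS2 agreement with a library/literature spectrum.
#' @param class_rule A diagnostic class rule (or in-silico match) fired.
#' @param has_formula A molecular formula could be assigned.
#' @return An ordered factor with levels I < II < III < IV < V.
#' @export
assign_level <- function(standard_match = FALSE, library_match = FALSE,
                         class_rule = FALSE, has_formula = FALSE) {
  stopifnot(is.logical(standard_match), is.logical(library_match),
            is.logical(class_rule), is.logical(has_formula))
  if (standard_match && !library_match) {
    stop("contradictory evidence: a standard match implies library-grade ",
         "MS2 agreement", call. = FALSE)
  }
  lvl <- if (standard_match) "I"
    else if (library_match) "II"
    else if (class_rule) "III"
    else if (has_formula) "IV"
    else "V"
  factor(lvl, levels = LEVELS, ordered = TRUE)
}

#' Recompute the confidence-level census of the packaged annotation table
#'
#' Maps each fixture row's evidence category through [assign_level()] and
#' tabulates the result. On the shipped table this reproduces the printed
#' census: 15 level-I, 66 level-II and 121 level-III compounds.
#'
#' @return A named integer vector of counts over levels I-V.
#' @export
annotate_fixture_rerun <- function() {
  tab <- load_table1_fixture()
  lv <- vapply(tab$evidence, function(ev) {
    as.character(assign_level(
      standard_match = ev == "standard_match",
      library_match = ev %in% c("standard_match", "library_match"),
      class_rule = ev == "class_rule",
      has_formula = TRUE
    ))
  }, character(1))
  counts <- table(factor(lv, levels = LEVELS))
  stats::setNames(as.integer(counts), LEVELS)
}
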