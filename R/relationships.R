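# Within a pseudo-spectrum, infer each feature's ion role relative to a
# neutral mass M, and reconcile M across ionization modes.

#' Infer ion roles within a feature group
#'
#' Every member of the group, interpreted under every registered
#' (non-isotopic) adduct, proposes a candidate neutral mass M. Each
#' candidate is scored by how many group members it explains as a
#' registered adduct, a 13C isotopologue (accepted only when the
#' monoisotopic partner is present and more intense), or an in-source
#' fragment of the (de)protonated ion through the registered neutral-loss
#' table. The M explaining the most members wins; ties prefer the
#' hypothesis whose (de)protonated ion is the group's most intense member,
#' then the smaller total |ppm| over explained members. Unexplained
#' members are retained with role `"unexplained"`.
#'
#' @param group A `feature_group`.
#' @param tol_ppm Mass tolerance in ppm (default 5, the instrument's
#'   external-calibration accuracy).
#' @return A `neutral_hypothesis`: a list with `M` (Da),
#'   `polarity_support`, `explained_count`, `rt_centroid` and
#'   `assignments`, a data frame with one row per member (`feature_id`,
#'   `mz`, `role`, `detail`, `isotope_k`, `ppm`). A singleton group is
#'   assigned the (de)protonated role with `flagged = TRUE`.
#' @export
infer_roles <- function(group, tol_ppm = 5) {
  stopifnot(inherits(group, "feature_group"), nrow(group$members) >= 1L)
  members <- group$members
  pol <- group$polarity
  reg <- adduct_registry()
  reg <- reg[reg$polarity == pol, ]
  base_reg <- reg[reg$isotope_shift == 0L, ]
  default_adduct <- if (pol == "-") "[M-H]-" else "[M+H]+"
  intens <- apply(intensity_matrix(members), 1L, max)

  # candidate neutral masses
  cand_M <- unlist(lapply(seq_len(nrow(members)), function(i) {
    vapply(seq_len(nrow(base_reg)), function(j) {
      neutral_mass_for_mz(members$mz[i], base_reg[j, ])
    }, numeric(1))
  }))
  cand_M <- cand_M[cand_M > 0]

  best <- NULL
  for (M in cand_M) {
    h <- explain_members(M, members, reg, pol, tol_ppm, intens)
    if (is.null(best) || better_hypothesis(h, best, members, intens,
                                           default_adduct)) {
      best <- h
    }
  }
  flagged <- FALSE
  if (nrow(members) == 1L && best$explained_count <= 1L) {
    # degenerate singleton: call it the (de)protonated ion, but flag it
    a <- get_adduct(default_adduct)
    M <- neutral_mass_for_mz(members$mz[1], a)
    best <- explain_members(M, members, reg, pol, tol_ppm, intens)
    flagged <- TRUE
  }
  structure(list(M = best$M,
                 polarity_support = pol,
                 explained_count = best$explained_count,
                 assignments = best$assignments,
                 rt_centroid = group$rt_centroid,
                 flagged = flagged),
            class = "neutral_hypothesis")
}

# score a candidate neutral mass against the group members
explain_members <- function(M, members, reg, pol, tol_ppm, intens) {
  losses <- neutral_losses()
  base_adduct <- if (pol == "-") "[M-H]-" else "[M+H]+"
  base_mz <- mz_for_neutral_mass(M, get_adduct(base_adduct))
  n <- nrow(members)
  role <- rep("unexplained", n)
  detail <- rep(NA_character_, n)
  iso_k <- rep(0L, n)
  ppm <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    mz_i <- members$mz[i]
    # adduct / isotope / multimer roles
    theo <- vapply(seq_len(nrow(reg)), function(j) {
      mz_for_neutral_mass(M, reg[j, ])
    }, numeric(1))
    dev <- ifelse(theo > 0, 1e6 * (mz_i - theo) / theo, Inf)
    ok <- which(abs(dev) <= tol_ppm)
    if (length(ok)) {
      # isotopologues need their monoisotopic partner, more intense
      ok <- Filter(function(j) {
        if (reg$isotope_shift[j] == 0L) return(TRUE)
        mono <- theo[j] - reg$isotope_shift[j] * C13_MASS_SHIFT /
          abs(reg$charge[j])
        if (mono <= 0) return(FALSE)
        partner <- which(abs(ppm_error(members$mz, mono)) <= tol_ppm)
        partner <- setdiff(partner, i)
        length(partner) > 0 && max(intens[partner]) > intens[i]
      }, ok)
    }
    if (length(ok)) {
      j <- ok[which.min(abs(dev[ok]))]
      iso_k[i] <- reg$isotope_shift[j]
      detail[i] <- reg$name[j]
      ppm[i] <- dev[j]
      role[i] <- if (reg$isotope_shift[j] > 0L) "isotope"
        else if (reg$multimer[j] > 1L) "multimer"
        else if (reg$name[j] == base_adduct) "molecular_ion"
        else "adduct"
      next
    }
    # in-source fragment: base ion minus a registered neutral loss
    frag_theo <- base_mz - losses$mass
    fdev <- ifelse(frag_theo > 0, 1e6 * (mz_i - frag_theo) / frag_theo, Inf)
    fok <- which(abs(fdev) <= tol_ppm)
    if (length(fok)) {
      j <- fok[which.min(abs(fdev[fok]))]
      role[i] <- "in_source_fragment"
      detail[i] <- losses$name[j]
      ppm[i] <- fdev[j]
    }
  }
  assignments <- data.frame(feature_id = members$feature_id,
                            mz = members$mz, role = role, detail = detail,
                            isotope_k = iso_k, ppm = ppm,
                            stringsAsFactors = FALSE)
  list(M = M, explained_count = sum(role != "unexplained"),
       assignments = assignments)
}

better_hypothesis <- function(a, b, members, intens, default_adduct) {
  if (a$explained_count != b$explained_count) {
    return(a$explained_count > b$explained_count)
  }
  # prefer the hypothesis whose (de)protonated ion is the base peak
  base_is_top <- function(h) {
    i <- which(h$assignments$role == "molecular_ion" &
                 h$assignments$isotope_k == 0L)
    length(i) > 0 && max(intens[i]) >= max(intens)
  }
  ta <- base_is_top(a); tb <- base_is_top(b)
  if (ta != tb) return(ta)
  sa <- sum(abs(a$assignments$ppm), na.rm = TRUE)
  sb <- sum(abs(b$assignments$ppm), na.rm = TRUE)
  sa < sb
}

#' @export
print.neutral_hypothesis <- function(x, ...) {
  cat("<neutral_hypothesis> M =", round(x$M, 5), "Da (",
      x$polarity_support, "),", x$explained_count, "of",
      nrow(x$assignments), "ions explained\n")
  invisible(x)
}

#' Reconcile neutral-mass hypotheses across ionization modes
#'
#' Adduct formation in the complementary ionization mode corroborates a
#' neutral mass: two hypotheses from opposite polarities are merged when
#' their masses agree within `tol_ppm` and their RT centroids within
#' `rt_window` seconds.
#'
#' @param neg,pos `neutral_hypothesis` objects of opposite polarity.
#' @param rt_window RT tolerance in seconds (default 5).
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @return A merged `neutral_hypothesis` with `polarity_support = c("-",
#'   "+")` and the intensity-unweighted mean M, or `NULL` when the
#'   hypotheses are incompatible.
#' @export
reconcile_polarities <- function(neg, pos, rt_window = 5, tol_ppm = 5) {
  stopifnot(inherits(neg, "neutral_hypothesis"),
            inherits(pos, "neutral_hypothesis"))
  if (identical(neg$polarity_support, pos$polarity_support)) {
    stop("hypotheses must come from opposite ionization modes",
         call. = FALSE)
  }
  if (abs(ppm_error(pos$M, neg$M)) > tol_ppm) return(NULL)
  if (abs(neg$rt_centroid - pos$rt_centroid) > rt_window) return(NULL)
  structure(list(M = mean(c(neg$M, pos$M)),
                 polarity_support = c("-", "+"),
                 explained_count = neg$explained_count + pos$explained_count,
                 assignments = rbind(neg$assignments, pos$assignments),
                 rt_centroid = mean(c(neg$rt_centroid, pos$rt_centroid)),
                 flagged = FALSE),
            class = "neutral_hypothesis")
}
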