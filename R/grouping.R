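# Cluster co-eluting, co-varying features into pseudo-spectra, per
# ionization mode.

#' Group co-eluting, correlated features into pseudo-spectra
#'
#' Features detected by peak picking are clustered when they elute at close
#' retention times and their per-sample intensity profiles are highly
#' correlated, so that each group collects the ions (adducts, isotopes,
#' in-source fragments) of one compound.
#'
#' The algorithm is deterministic and independent of input order: features
#' are visited in decreasing order of their maximum intensity (ties broken
#' by m/z); each feature joins the first existing group whose seed (the
#' group's most intense member) is within `rt_window` seconds and whose
#' seed correlation is at least `min_corr`; among several qualifying seeds
#' the one with the smaller RT gap, then the smaller m/z gap, wins.
#' Otherwise the feature seeds a new group. Correlation is Pearson on
#' log10(intensity + 1) across samples; with fewer than 3 samples the
#' correlation criterion is skipped with a warning.
#'
#' @param features A `feature_table` (single polarity).
#' @param rt_window Maximum |RT - seed RT| in seconds (default 5).
#' @param min_corr Minimum Pearson correlation with the group seed on
#'   log10 intensities (default 0.8).
#' @return A list of `feature_group` objects; each has `group_id`,
#'   `polarity`, `members` (rows of `features`) and `rt_centroid` (the seed
#'   retention time). Every input feature belongs to exactly one group.
#' @export
group_features <- function(features, rt_window = 5, min_corr = 0.8) {
  stopifnot(nrow(features) >= 1L)
  if (length(unique(features$polarity)) > 1L) {
    stop("mixed polarities; group each ionization mode separately",
         call. = FALSE)
  }
  m <- intensity_matrix(features)
  use_corr <- ncol(m) >= 3L
  if (!use_corr) {
    warning("fewer than 3 samples: correlation criterion skipped")
  }
  logm <- log10(m + 1)
  peak <- apply(m, 1L, max)
  ord <- order(-peak, features$mz)

  seed_idx <- integer(0)       # row index of each group's seed
  assignment <- integer(nrow(features))
  for (i in ord) {
    cand <- seed_idx[abs(features$rt[seed_idx] - features$rt[i]) <= rt_window]
    if (use_corr && length(cand)) {
      ok <- vapply(cand, function(s) {
        r <- suppressWarnings(stats::cor(logm[s, ], logm[i, ]))
        !is.na(r) && r >= min_corr
      }, logical(1))
      cand <- cand[ok]
    }
    if (length(cand)) {
      drt <- abs(features$rt[cand] - features$rt[i])
      dmz <- abs(features$mz[cand] - features$mz[i])
      best <- cand[order(drt, dmz)][1]
      assignment[i] <- assignment[best]
    } else {
      seed_idx <- c(seed_idx, i)
      assignment[i] <- length(seed_idx)
    }
  }
  lapply(seq_along(seed_idx), function(g) {
    members <- features[assignment == g, , drop = FALSE]
    new_feature_group(
      group_id = sprintf("G%03d", g),
      polarity = features$polarity[1],
      members = members,
      rt_centroid = features$rt[seed_idx[g]]
    )
  })
}

new_feature_group <- function(group_id, polarity, members, rt_centroid) {
  structure(list(group_id = group_id, polarity = polarity,
                 members = members, rt_centroid = rt_centroid),
            class = "feature_group")
}

#' @export
print.feature_group <- function(x, ...) {
  cat("<feature_group> ", x$group_id, " (", x$polarity, ") ",
      nrow(x$members), " features @ ", round(x$rt_centroid, 1), " s\n",
      sep = "")
  invisible(x)
}
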