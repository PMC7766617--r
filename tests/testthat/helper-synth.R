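# Shared fixture builders; everything is generated in code at test time.

toy_features <- function(mzs, rt, intensities, polarity = "-",
                         ids = sprintf("f%02d", seq_along(mzs))) {
  stopifnot(nrow(intensities) == length(mzs))
  df <- data.frame(feature_id = ids, mz = mzs,
                   rt = rep_len(rt, length(mzs)), polarity = polarity,
                   stringsAsFactors = FALSE)
  colnames(intensities) <- paste0("intensity_",
                                  if (is.null(colnames(intensities)))
                                    letters[seq_len(ncol(intensities))]
                                  else colnames(intensities))
  df <- cbind(df, intensities)
  class(df) <- c("feature_table", "data.frame")
  df
}

toy_spectrum <- function(mzs, intensities = NULL, precursor = 500,
                         polarity = "-", rt = 100) {
  if (is.null(intensities)) intensities <- rep(1, length(mzs))
  peaks <- cbind(mz = mzs, intensity = intensities / max(intensities, 1))
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  olivemet:::new_ms2_spectrum(precursor, polarity, rt, peaks)
}

# a small deterministic compound library drawn from the packaged table
synth_library <- function(n = 8, seed = 7) {
  tab <- load_table1_fixture()
  set.seed(seed)
  tab[sample(nrow(tab), n), c("name", "formula", "rt_s")]
}

# map an assignments data frame to planted-truth role strings
predicted_roles <- function(assignments) {
  ifelse(assignments$role == "in_source_fragment",
         paste0("frag:", assignments$detail), assignments$detail)
}
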