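# Readers/writers for feature tables and MS2 spectra, and loaders for the
# packaged reference tables (annotations, calibration parameters,
# concentration ranges, product metadata).

#' Read a per-sample LC-MS feature table
#'
#' The expected layout is delimited text with columns `feature_id`, `mz`,
#' `rt` (seconds) and one `intensity_<sample>` column per sample, as written
#' by [write_feature_table()] or [simulate_feature_tables()].
#'
#' @param path Path to a delimited text file.
#' @param polarity Ionization mode of the table, `"+"` or `"-"`.
#' @param sep Field separator, default tab.
#' @return A `feature_table`: a data frame with columns `feature_id`, `mz`,
#'   `rt`, `polarity` and the intensity columns, one row per detected ion.
#' @export
read_feature_table <- function(path, polarity = c("-", "+"), sep = "\t") {
  polarity <- match.arg(polarity)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("feature_id", "mz", "rt")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  int_cols <- grep("^intensity_", names(df), value = TRUE)
  if (!length(int_cols)) {
    stop("feature table has no intensity_<sample> columns", call. = FALSE)
  }
  df$feature_id <- as.character(df$feature_id)
  for (col in c("mz", "rt", int_cols)) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric values in column '", col, "'", call. = FALSE)
    }
  }
  validate_features(df, int_cols)
  df$polarity <- polarity
  df <- df[c("feature_id", "mz", "rt", "polarity", int_cols)]
  class(df) <- c("feature_table", "data.frame")
  df
}

validate_features <- function(df, int_cols) {
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (any(df$mz <= 0)) stop("m/z values must be positive", call. = FALSE)
  if (any(df$rt < 0)) stop("retention times must be >= 0", call. = FALSE)
  if (any(as.matrix(df[int_cols]) < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_feature_table
#' @param features A `feature_table` data frame.
#' @export
write_feature_table <- function(features, path, sep = "\t") {
  out <- features[setdiff(names(features), "polarity")]
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the intensity matrix of a feature table
#'
#' @param features A `feature_table`.
#' @return A numeric matrix, features x samples, with the `intensity_`
#'   prefix stripped from the column names.
#' @export
intensity_matrix <- function(features) {
  int_cols <- grep("^intensity_", names(features), value = TRUE)
  m <- as.matrix(features[int_cols])
  rownames(m) <- features$feature_id
  colnames(m) <- sub("^intensity_", "", int_cols)
  m
}

# ---- MGF -------------------------------------------------------------------

#' Read MS2 spectra from an MGF file
#'
#' Understands the common MGF dialect: `BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, optional `CHARGE` (sign gives the polarity) and `RTINSECONDS`
#' headers followed by `m/z intensity` peak lines. Peaks are sorted by m/z
#' and intensities rescaled to a maximum of 1 on load. A block without
#' peaks is kept (with a warning); a block without a precursor is an error.
#'
#' @param path Path to an MGF file.
#' @return A list of `ms2_spectrum` objects, each a list with elements
#'   `precursor_mz`, `polarity`, `rt` and `peaks` (two-column matrix `mz`,
#'   `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) {
    stop("unbalanced BEGIN IONS/END IONS blocks", call. = FALSE)
  }
  spectra <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    headers <- grep("^[A-Z]+=", block, value = TRUE)
    peak_lines <- grep("^[0-9]", block, value = TRUE)
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), headers, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    pepmass <- get("PEPMASS")
    if (is.na(pepmass)) {
      stop("MGF block ", i, " has no PEPMASS", call. = FALSE)
    }
    precursor <- as.numeric(strsplit(pepmass, "[ \t]")[[1]][1])
    charge <- get("CHARGE")
    polarity <- if (!is.na(charge) && grepl("-", charge, fixed = TRUE)) "-"
                else "+"
    rt <- as.numeric(get("RTINSECONDS"))
    if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      peaks <- cbind(mz = as.numeric(vapply(fields, `[`, "", 1L)),
                     intensity = as.numeric(vapply(fields, `[`, "", 2L)))
      peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
      peaks[, "intensity"] <- peaks[, "intensity"] / max(peaks[, "intensity"])
    } else {
      warning("MGF block ", i, " has an empty peak list")
      peaks <- cbind(mz = numeric(0), intensity = numeric(0))
    }
    spectra[[i]] <- new_ms2_spectrum(precursor, polarity, rt, peaks)
  }
  spectra
}

new_ms2_spectrum <- function(precursor_mz, polarity, rt, peaks) {
  structure(list(precursor_mz = precursor_mz, polarity = polarity,
                 rt = rt, peaks = peaks),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> precursor", round(x$precursor_mz, 4), x$polarity,
      "rt", x$rt, "s,", nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' @rdname read_mgf
#' @param spectra List of `ms2_spectrum` objects.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(paste0("CHARGE=1", s$polarity), con)
    if (!is.null(s$rt) && !is.na(s$rt)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$rt), con)
    }
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.6f %.6f", s$peaks[, "mz"],
                         s$peaks[, "intensity"]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

# ---- Packaged fixtures -----------------------------------------------------

FIXTURE_CHECKSUMS <- c(
  table1_annotations.tsv    = "066537d097a7484764ce574a9cda4a75",
  table2_calibration.tsv    = "69a50916a1c1b273d397d80382c9fa31",
  table3_concentrations.tsv = "97be940774e54fd36e2df26e343a757e",
  table4_products.tsv       = "115f5f437737dd7c739b285d70496e39",
  targeted_compounds.tsv    = "9f31701f0188cb87a54f2b3d66ee80ed"
)

fixture_path <- function(fname) {
  p <- system.file("extdata", fname, package = "olivemet")
  if (p == "") stop("packaged fixture not found: ", fname, call. = FALSE)
  p
}

check_fixture <- function(fname) {
  p <- fixture_path(fname)
  sum <- unname(tools::md5sum(p))
  if (!identical(sum, unname(FIXTURE_CHECKSUMS[[fname]]))) {
    stop(fixture_integrity_error(fname, sum))
  }
  p
}

fixture_integrity_error <- function(fname, sum) {
  structure(
    class = c("fixture_integrity_error", "error", "condition"),
    list(message = paste0("fixture checksum mismatch for ", fname,
                          " (got ", sum, ")"),
         call = NULL)
  )
}

#' Load the packaged annotation table (202 compounds)
#'
#' The transcribed census of annotated constituents of the 14 supplements:
#' compound id (C001-C202), name, molecular formula, retention time in
#' seconds, the printed ion list (semicolon-separated `"m/z label"`
#' entries), and the confidence level (I, II or III) with its evidence
#' category. The file integrity is verified with an MD5 checksum so tests
#' never depend on network resources.
#'
#' @return A data frame with 202 rows and columns `compound_id`, `name`,
#'   `formula`, `rt_s`, `ions`, `level`, `evidence`.
#' @export
load_table1_fixture <- function() {
  p <- check_fixture("table1_annotations.tsv")
  df <- utils::read.delim(p, stringsAsFactors = FALSE, quote = "")
  stopifnot(nrow(df) == 202L)
  df
}

#' Parse the ion-list column of the annotation table
#'
#' @param ions A single semicolon-separated ion-list string, e.g.
#'   `"153.0558 [M-H]-; 154.0592 13C[M-H]-"`.
#' @return A data frame with columns `mz`, `label` and `kind`; `kind` is
#'   `"adduct"` when the label is in the registry, `"fragment"` when it is a
#'   bracketed loss expression, otherwise `"other"` (the table also carries
#'   unstructured labels such as `[frag]-` or `[add-1]-`).
#' @export
parse_ion_entries <- function(ions) {
  entries <- strsplit(ions, ";[ ]*")[[1]]
  entries <- entries[nzchar(entries)]
  mz <- as.numeric(sub(" .*$", "", entries))
  label <- sub("^[0-9.]+ ", "", entries)
  registered <- label %in% adduct_registry()$name
  fragment <- !registered & grepl("^(\\(2\\))?(13C)?\\[[0-9]?M[+-]", label)
  kind <- ifelse(registered, "adduct", ifelse(fragment, "fragment", "other"))
  data.frame(mz = mz, label = label, kind = kind, stringsAsFactors = FALSE)
}

#' Load the packaged calibration-parameter table
#'
#' Calibration parameters of the 12 analytes with available standards:
#' detector (MS or DAD), linear dynamic range in mg/L, intercept, slope and
#' R-squared of the calibration line, and the three validation relative
#' standard deviations (intra-day, inter-day, operator repeatability, %).
#'
#' @return A data frame with 12 rows.
#' @export
load_table2_fixture <- function() {
  p <- check_fixture("table2_calibration.tsv")
  utils::read.delim(p, stringsAsFactors = FALSE, quote = "")
}

#' Parse a printed concentration-range cell
#'
#' The concentration table prints per-product ranges as `"a-b"` (measured),
#' `"<LOQ"` (below the limit of quantification), `"ND"` (not detected),
#' `"LOQ-b"` / `"ND-b"` (some replicates unquantifiable) or `"ND-<LOQ"`.
#' For totalling purposes unquantifiable values count as zero: `ND`,
#' `<LOQ` and `ND-<LOQ` give `lo = hi = 0`; `LOQ-b` and `ND-b` give
#' `lo = 0, hi = b`.
#'
#' @param raw Character vector of range cells.
#' @return A data frame with columns `lo`, `hi` (mg/g) and `censoring`
#'   (one of `measured`, `below_loq`, `not_detected`, `mixed`).
#' @export
parse_conc_range <- function(raw) {
  raw <- gsub("–", "-", trimws(raw))  # en dash -> hyphen
  one <- function(x) {
    if (x == "ND") return(c(0, 0, "not_detected"))
    if (x == "<LOQ") return(c(0, 0, "below_loq"))
    if (x == "ND-<LOQ") return(c(0, 0, "mixed"))
    if (grepl("^(ND|LOQ)-", x)) {
      hi <- as.numeric(sub("^(ND|LOQ)-", "", x))
      if (is.na(hi)) stop("unparseable range cell: '", x, "'", call. = FALSE)
      return(c(0, hi, "mixed"))
    }
    parts <- strsplit(x, "-", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || anyNA(vals) || vals[1] > vals[2]) {
      stop("unparseable range cell: '", x, "'", call. = FALSE)
    }
    c(vals[1], vals[2], "measured")
  }
  parsed <- t(vapply(raw, one, character(3)))
  data.frame(lo = as.numeric(parsed[, 1]), hi = as.numeric(parsed[, 2]),
             censoring = parsed[, 3], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Load the packaged concentration-range table (26 compounds x 14 products)
#'
#' @return A data frame in long format with columns `compound`, `product`,
#'   `range_raw`, `lo`, `hi` (mg/g) and `censoring`.
#' @export
load_table3_fixture <- function() {
  p <- check_fixture("table3_concentrations.tsv")
  df <- utils::read.delim(p, stringsAsFactors = FALSE, quote = "")
  stopifnot(length(unique(df$compound)) == 26L,
            length(unique(df$product)) == 14L)
  cbind(df, parse_conc_range(df$range_raw))
}

#' Load the packaged product-metadata table (14 products)
#'
#' Product code, plant part used, pharmaceutical form, the supplier's
#' recommended daily intake converted to grams per day, whether other plant
#' extracts are present, and the extraction process.
#'
#' @return A data frame with 14 rows.
#' @export
load_table4_fixture <- function() {
  p <- check_fixture("table4_products.tsv")
  df <- utils::read.delim(p, stringsAsFactors = FALSE, quote = "")
  stopifnot(nrow(df) == 14L, all(df$daily_dose_g > 0))
  df
}

#' Load the targeted-compound metadata
#'
#' For each of the 26 quantified compounds: the surrogate calibration
#' standard it is expressed as (compounds without their own standard are
#' expressed as oleuropein, except hydroxytyrosol glucoside as
#' hydroxytyrosol, hydroxy-verbascoside as verbascoside and
#' trihydroxyoctadecenoic acid as isocitric acid) and whether it is
#' phenolic.
#'
#' @return A data frame with columns `compound`, `surrogate_standard`,
#'   `phenolic` (`"yes"`/`"no"`).
#' @export
load_targeted_compounds <- function() {
  p <- check_fixture("targeted_compounds.tsv")
  utils::read.delim(p, stringsAsFactors = FALSE, quote = "")
}
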