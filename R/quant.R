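# Calibration fitting, LOQ/LDR handling, back-calculation to mg/g, and
# validation RSDs.

#' Fit a calibration curve with linear-dynamic-range detection
#'
#' An ordinary least-squares line through the calibration points. The
#' linear dynamic range (LDR) is the widest contiguous run of calibration
#' levels (ties broken towards the lower start) whose back-calculated
#' concentrations agree with the nominal ones within +/-20 percent; the
#' curve is then rebuilt on those levels and R-squared recomputed. The
#' limit of quantification (LOQ) is the lowest level inside the LDR.
#'
#' @param concentration Nominal concentrations in mg/L (>= 5 distinct
#'   values).
#' @param response Detector responses (same length).
#' @param accuracy_tol Back-calculated accuracy tolerance defining the LDR
#'   (default 0.2, i.e. +/-20 percent).
#' @param analyte,detector Optional labels stored on the curve.
#' @return A `calibration_curve`: list with `analyte`, `detector`,
#'   `points`, `slope`, `intercept`, `r2`, `ldr` (`c(lo, hi)` mg/L) and
#'   `loq` (mg/L).
#' @export
fit_calibration <- function(concentration, response, accuracy_tol = 0.2,
                            analyte = NA_character_, detector = "MS") {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 5L) {
    stop("need at least 5 distinct calibration levels", call. = FALSE)
  }
  if (stats::sd(response) == 0) {
    stop("constant responses: no calibration possible", call. = FALSE)
  }
  fit_line <- function(x, y) {
    f <- stats::lm(y ~ x)
    # R^2 computed directly; summary.lm warns on noiseless lines
    r2 <- 1 - sum(stats::residuals(f)^2) / sum((y - mean(y))^2)
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r2 = r2)
  }
  full <- fit_line(concentration, response)
  levels_sorted <- sort(unique(concentration))
  acc_ok <- vapply(levels_sorted, function(lv) {
    y <- response[concentration == lv]
    back <- (mean(y) - full$intercept) / full$slope
    abs(back - lv) <= accuracy_tol * lv
  }, logical(1))
  # widest contiguous TRUE run
  runs <- rle(acc_ok)
  if (!any(runs$values)) {
    stop("no contiguous calibration range meets the accuracy criterion",
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  idx <- starts[best]:ends[best]
  ldr_levels <- levels_sorted[idx]
  inside <- concentration %in% ldr_levels
  refit <- if (length(unique(concentration[inside])) >= 2L) {
    fit_line(concentration[inside], response[inside])
  } else full
  structure(list(analyte = analyte, detector = detector,
                 points = data.frame(concentration = concentration,
                                     response = response),
                 slope = refit$slope, intercept = refit$intercept,
                 r2 = refit$r2,
                 ldr = c(lo = min(ldr_levels), hi = max(ldr_levels)),
                 loq = min(ldr_levels)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>", if (!is.na(x$analyte)) x$analyte else "",
      sprintf("(%s): response = %.4g * c %+.4g, R2 = %.4f\n",
              x$detector, x$slope, x$intercept, x$r2))
  cat("  LDR", x$ldr[["lo"]], "-", x$ldr[["hi"]], "mg/L, LOQ",
      x$loq, "mg/L\n")
  invisible(x)
}

#' Back-calculate a sample concentration from a detector response
#'
#' Inverts the calibration line and divides by the sample preparation
#' dilution (500 mg to 5 mL gives 100 g/L; the alternative dilute
#' preparation is 2 g/L). Responses mapping below the LOQ are censored
#' (`below_loq`, concentration 0); non-positive back-calculated values are
#' `not_detected`.
#'
#' @param response Detector response(s), >= 0.
#' @param curve A `calibration_curve`.
#' @param dilution_g_per_L Sample preparation concentration in g/L
#'   (default 100).
#' @return A data frame with columns `conc_mg_per_g` and `censoring`
#'   (`quantified`, `below_loq` or `not_detected`).
#' @export
back_calculate <- function(response, curve, dilution_g_per_L = 100) {
  stopifnot(inherits(curve, "calibration_curve"), all(response >= 0))
  if (curve$slope <= 0) stop("non-positive calibration slope", call. = FALSE)
  conc_mgL <- (response - curve$intercept) / curve$slope
  censoring <- ifelse(conc_mgL <= 0, "not_detected",
                      ifelse(conc_mgL < curve$loq, "below_loq", "quantified"))
  value <- ifelse(censoring == "quantified", conc_mgL / dilution_g_per_L, 0)
  data.frame(conc_mg_per_g = value, censoring = censoring,
             stringsAsFactors = FALSE)
}

#' Choose the sample dilution for a predicted response
#'
#' The concentrated preparation (100 g/L) is preferred; the dilute one
#' (2 g/L) is selected only when the predicted concentration exceeds the
#' curve's linear dynamic range.
#'
#' @param predicted_conc_mgL Predicted analyte concentration (mg/L) of the
#'   100 g/L preparation.
#' @param curve A `calibration_curve`.
#' @return 100 or 2 (g/L).
#' @export
select_dilution <- function(predicted_conc_mgL, curve) {
  ifelse(predicted_conc_mgL > curve$ldr[["hi"]], 2, 100)
}

#' Relative standard deviation in percent
#'
#' @param values Numeric vector with at least two values and nonzero mean.
#' @return `100 * sd(values) / mean(values)` (sample standard deviation).
#' @export
rsd_percent <- function(values) {
  if (length(values) < 2L) {
    stop("need at least two values for an RSD", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("zero mean: RSD undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Method-validation report (intra-day, inter-day, repeatability RSDs)
#'
#' Mirrors the layout of the packaged calibration table: per compound, the
#' RSD of 7 consecutive same-day injections (intra-day), of injections on
#' 5 consecutive days (inter-day), and of 7 independently prepared
#' solutions (operator repeatability).
#'
#' @param intra Named list, one numeric vector of length 7 per compound.
#' @param inter Named list of length-5 vectors (same compounds).
#' @param repeatability Named list of length-7 vectors (same compounds).
#' @return A data frame with columns `compound`, `rsd_intra_day`,
#'   `rsd_inter_day`, `rsd_repeatability` (percent).
#' @export
validation_report <- function(intra, inter, repeatability) {
  compounds <- names(intra)
  if (!setequal(compounds, names(inter)) ||
      !setequal(compounds, names(repeatability))) {
    stop("the three replicate sets must cover the same compounds",
         call. = FALSE)
  }
  check_n <- function(lst, n, label) {
    bad <- names(lst)[vapply(lst, length, integer(1)) != n]
    if (length(bad)) {
      stop(label, " requires ", n, " replicates; wrong count for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_n(intra, 7L, "intra-day repeatability")
  check_n(inter, 5L, "inter-day variability")
  check_n(repeatability, 7L, "operator repeatability")
  data.frame(
    compound = compounds,
    rsd_intra_day = vapply(intra[compounds], rsd_percent, numeric(1)),
    rsd_inter_day = vapply(inter[compounds], rsd_percent, numeric(1)),
    rsd_repeatability = vapply(repeatability[compounds], rsd_percent,
                               numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
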