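# Multivariate overview and group-difference testing: log/Pareto
# preprocessing, PCA, Kruskal-Wallis with Benjamini-Hochberg correction,
# and heat-map ordering with class-behavior labels.

#' Log-transform and Pareto-scale an abundance matrix
#'
#' Each cell becomes `log10(x + epsilon)`; each column (compound) is then
#' mean-centered and divided by the square root of its standard deviation
#' (Pareto scaling). Missing cells are first imputed with a seeded uniform
#' draw between 0 and one tenth of the column's smallest positive value,
#' emulating the replacement of missing values by a random very low value.
#' Constant columns scale to zero.
#'
#' @param m Non-negative numeric matrix, samples x compounds; may contain
#'   `NA`.
#' @param epsilon Offset added before the log (default 1; abundances are in
#'   arbitrary detector units).
#' @param seed Seed for the imputation draws (default 1).
#' @return The scaled matrix.
#' @export
preprocess <- function(m, epsilon = 1, seed = 1) {
  stopifnot(is.matrix(m))
  if (any(m < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (anyNA(m)) {
    set.seed(seed)
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (!any(nas)) next
      pos <- m[, j][!nas & m[, j] > 0]
      if (!length(pos)) {
        stop("column ", j, " has no observed positive value to impute from",
             call. = FALSE)
      }
      m[nas, j] <- stats::runif(sum(nas), 0, min(pos) / 10)
    }
  }
  lm_ <- log10(m + epsilon)
  centered <- sweep(lm_, 2L, colMeans(lm_))
  sds <- apply(lm_, 2L, stats::sd)
  scl <- ifelse(sds > 0, sqrt(sds), 1)  # sd guard: constant -> zero column
  sweep(centered, 2L, scl, "/")
}

#' Principal component analysis overview
#'
#' Singular-value-decomposition PCA of an already-scaled matrix (see
#' [preprocess()]); no further centering or scaling is applied.
#'
#' @param scaled Numeric matrix, samples x compounds, at least 3 rows.
#' @return A list with `scores`, `loadings` and `explained` (per-component
#'   variance fractions, summing to at most 1).
#' @export
pca_overview <- function(scaled) {
  stopifnot(is.matrix(scaled), nrow(scaled) >= 3L)
  if (all(scaled == 0)) stop("rank-0 matrix", call. = FALSE)
  p <- stats::prcomp(scaled, center = FALSE, scale. = FALSE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, explained = explained)
}

#' Kruskal-Wallis tests with Benjamini-Hochberg correction
#'
#' One Kruskal-Wallis test per feature (column) against the class labels;
#' p-values are adjusted with the Benjamini-Hochberg procedure and
#' significance is declared at `alpha`.
#'
#' @param m Numeric matrix, samples x features.
#' @param classes Class label per sample; at least 2 classes with at least
#'   2 members each.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return A data frame with columns `feature`, `p`, `p_adj`,
#'   `significant`.
#' @export
kw_bh <- function(m, classes, alpha = 0.05) {
  stopifnot(is.matrix(m), length(classes) == nrow(m))
  classes <- factor(classes)
  if (nlevels(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(classes) < 2L)) {
    stop("every class needs at least 2 members", call. = FALSE)
  }
  p <- vapply(seq_len(ncol(m)), function(j) {
    stats::kruskal.test(m[, j], classes)$p.value
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  feature <- if (!is.null(colnames(m))) colnames(m)
             else paste0("F", seq_len(ncol(m)))
  data.frame(feature = feature, p = p, p_adj = p_adj,
             significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Heat-map ordering and class-behavior labels
#'
#' Columns (samples) are ordered by class; each row (feature) is labelled
#' by the ordering of its class median abundances, e.g. `"F > L > B"`,
#' with `"="` joining tied classes. Rows are ordered by label so that
#' features behaving alike sit together.
#'
#' @param m Numeric matrix, samples x features (the significant set).
#' @param classes Class label per sample (rows of `m`).
#' @return A list with `col_order`, `row_order` and `row_labels`.
#' @export
heatmap_order <- function(m, classes) {
  stopifnot(is.matrix(m), length(classes) == nrow(m))
  if (!ncol(m)) stop("empty significant set", call. = FALSE)
  classes <- factor(classes, levels = unique(classes))
  col_order <- order(classes)
  labels <- vapply(seq_len(ncol(m)), function(j) {
    med <- tapply(m[, j], classes, stats::median)
    behavior_label(med)
  }, character(1))
  row_order <- order(labels)
  list(col_order = col_order, row_order = row_order, row_labels = labels)
}

behavior_label <- function(medians) {
  ord <- order(-medians)
  sorted <- medians[ord]
  seps <- ifelse(diff(sorted) == 0, " = ", " > ")
  paste0(names(sorted), c(seps, ""), collapse = "")
}
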