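#' Principal component analysis on unit-variance-scaled data
#'
#' Columns are centred and scaled to unit variance before the
#' decomposition, so every metabolite contributes equally regardless of
#' concentration magnitude. Run on the full metabolite set before
#' selection and on the selected subset after, to see how much
#' between-group separation the selection concentrates on PC1. The sign
#' of each component is fixed by the convention that the
#' largest-magnitude loading entry is positive, making scores
#' reproducible across runs and platforms.
#'
#' @param mat numeric matrix, samples x metabolites (typically residuals).
#' @param metabolite_subset optional character vector restricting the
#'   columns.
#' @param n_components number of components to keep (default: all).
#' @return object of class `PCAResult`: `scores` (samples x components),
#'   `loadings` (metabolites x components, orthonormal columns),
#'   `explained_variance_frac`, and `dropped` (metabolites removed for NA
#'   or zero variance).
#' @export
run_pca <- function(mat, metabolite_subset = NULL, n_components = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(metabolite_subset)) {
    miss <- setdiff(metabolite_subset, colnames(mat))
    if (length(miss) > 0) {
      stop("unknown metabolite(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    mat <- mat[, metabolite_subset, drop = FALSE]
  }
  if (nrow(mat) < 2) stop("PCA requires >= 2 samples", call. = FALSE)
  dropped <- character(0)
  has_na <- colSums(is.na(mat)) > 0
  if (any(has_na)) {
    warning(sum(has_na), " metabolite(s) with NA values dropped before PCA")
    dropped <- c(dropped, colnames(mat)[has_na])
    mat <- mat[, !has_na, drop = FALSE]
  }
  zero_var <- apply(mat, 2, stats::sd) == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance metabolite(s) dropped before PCA")
    dropped <- c(dropped, colnames(mat)[zero_var])
    mat <- mat[, !zero_var, drop = FALSE]
  }
  if (ncol(mat) < 1) stop("no metabolites left for PCA", call. = FALSE)

  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- min(n_components %||% length(ev), length(ev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| entry positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = scores,
    loadings = loadings,
    explained_variance_frac = frac[seq_len(k)],
    explained_variance_frac_all = frac,
    dropped = dropped
  ), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  ev <- utils::head(x$explained_variance_frac, 5)
  cat("explained variance:",
      paste(sprintf("PC%d=%.1f%%", seq_along(ev), 100 * ev),
            collapse = ", "), "\n")
  invisible(x)
}
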