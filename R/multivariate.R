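#' Principal component analysis of samples
#'
#' PCA of the samples in protein space via singular value decomposition of
#' the centred (and by default scaled) data matrix. Proteins with zero
#' variance across samples carry no information and break scaling; they
#' are dropped with a warning when `scale = TRUE`. When the input still
#' contains missing cells, supply a completed matrix — the pipeline uses
#' the across-cycle mean of the imputed cycles for stability.
#'
#' @param values Complete numeric matrix, proteins x samples.
#' @param center,scale Passed to the SVD preprocessing (defaults `TRUE`,
#'   matching centred-and-scaled PCA).
#' @return Object of class `lfq_pca`: list with `scores`
#'   (samples x components), `loadings` (proteins x components,
#'   orthonormal columns) and `variance_explained` (proportions summing
#'   to 1 over the computed components).
#' @export
lfq_pca <- function(values, center = TRUE, scale = TRUE) {
  if (ncol(values) < 2L) stop("PCA needs at least 2 samples")
  if (anyNA(values)) stop("PCA needs a complete matrix; impute first")
  if (scale) {
    v <- apply(values, 1L, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance protein(s) dropped before scaling")
      values <- values[v > 0, , drop = FALSE]
    }
  }
  pc <- stats::prcomp(t(values), center = center, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x,
    loadings = pc$rotation,
    variance_explained = ve
  ), class = "lfq_pca")
}

#' @export
print.lfq_pca <- function(x, ...) {
  cat("lfq_pca:", nrow(x$scores), "samples,",
      length(x$variance_explained), "components\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5L)),
             collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation distance matrix
#'
#' Pairwise dissimilarity `d = 1 - r` (or `1 - |r|`) from the Pearson
#' correlation between items, the metric behind correlation-based heatmap
#' clustering. Range \[0, 2\] (or \[0, 1\]), symmetric, zero diagonal.
#'
#' @param values Numeric matrix.
#' @param axis Cluster `"rows"` (proteins, default) or `"columns"`
#'   (samples).
#' @param absolute Use `1 - |r|` so that strong anti-correlation also
#'   counts as proximity. Default `FALSE` (plain `1 - r`).
#' @return Symmetric numeric distance matrix with item names.
#' @export
correlation_distance <- function(values, axis = c("rows", "columns"),
                                 absolute = FALSE) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") t(values) else values
  if (ncol(x) < 2L) stop("need at least 2 items to compute distances")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance item: ", colnames(x)[which(v == 0)[1L]])
  r <- stats::cor(x)
  d <- if (absolute) 1 - abs(r) else 1 - r
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the pair of clusters with the smallest mean pairwise
#' inter-cluster distance at each step (unweighted average linkage).
#' Delegates to [stats::hclust()] with `method = "average"`, returning the
#' standard `hclust` object (`merge`, `height`, `order`), which plots and
#' cuts with the usual tools.
#'
#' @param d Symmetric distance matrix (e.g. from [correlation_distance()])
#'   or a `dist` object.
#' @return An `hclust` object.
#' @export
average_linkage <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Cluster an intensity matrix for heatmap display
#'
#' Convenience wrapper running the same UPGMA engine under either metric:
#' Pearson correlation distance (the default, matching the methods) or
#' Euclidean distance (the variant used for the expression heatmap).
#' Metric and linkage are orthogonal: only the distance changes.
#'
#' @param values Complete numeric matrix, proteins x samples.
#' @param axis `"rows"` or `"columns"`.
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @param absolute For the Pearson metric, use `1 - |r|`.
#' @return An `hclust` object.
#' @export
cluster_intensity <- function(values, axis = c("rows", "columns"),
                              metric = c("pearson", "euclidean"),
                              absolute = FALSE) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  if (metric == "pearson") {
    average_linkage(correlation_distance(values, axis, absolute))
  } else {
    x <- if (axis == "rows") values else t(values)
    average_linkage(stats::dist(x, method = "euclidean"))
  }
}
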