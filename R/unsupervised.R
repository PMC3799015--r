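#' Filter features on expression level and dynamic range
#'
#' Keeps features with at least one log2 value above `min_log2` and a
#' fold change above `min_fold` across all samples (max - min >
#' log2(min_fold)). Defaults reproduce the standard microarray
#' pre-filter: level > 5 on the log2 scale, fold change > 2.
#'
#' @param study an `ExpressionStudy`.
#' @param min_log2 minimum of the per-feature maximum log2 value.
#' @param min_fold minimum fold change (> 1) across all samples.
#' @return The filtered `ExpressionStudy`.
#' @export
filter_features <- function(study, min_log2 = 5, min_fold = 2) {
  if (min_fold <= 1) stop_("min_fold must be > 1")
  hi <- apply(study$exprs, 1, max)
  lo <- apply(study$exprs, 1, min)
  keep <- hi > min_log2 & (hi - lo) > log2(min_fold)
  if (!any(keep)) {
    stop_("no feature passes the filter; lower min_log2 (", min_log2,
          ") or min_fold (", min_fold, ")")
  }
  expression_study(study$exprs[keep, , drop = FALSE], study$samples)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Complete-linkage (default) agglomeration of samples under either
#' euclidean distance or 1 - Pearson correlation, the two metrics in
#' common use for expression heatmaps. Merge heights of complete
#' linkage are monotone non-decreasing; this is asserted.
#'
#' @param study an `ExpressionStudy`.
#' @param linkage agglomeration rule passed to [stats::hclust()].
#' @param metric `"pearson"` (1 - Pearson correlation between samples)
#'   or `"euclidean"`.
#' @return An object of class `Dendrogram` wrapping the `hclust` fit
#'   (`merge`, `height`, `order`, `labels`).
#' @export
hierarchical_cluster <- function(study, linkage = "complete",
                                 metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  x <- study$exprs
  if (ncol(x) < 2) stop_("need >= 2 samples to cluster")
  if (any(!is.finite(x))) stop_("non-finite values in expression matrix")
  d <- switch(metric,
              pearson = stats::as.dist(1 - stats::cor(x)),
              euclidean = stats::dist(t(x)))
  if (any(is.na(d))) {
    stop_("distance matrix contains NaN (zero-variance sample under the ",
          "correlation metric?)")
  }
  hc <- stats::hclust(d, method = linkage)
  if (linkage == "complete" && is.unsorted(hc$height)) {
    stop_("internal error: non-monotone complete-linkage merge heights")
  }
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, linkage = linkage, metric = metric,
                 hclust = hc), class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat("Dendrogram:", length(x$labels), "leaves,", x$linkage, "linkage,",
      x$metric, "metric\n")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#' @param dend a `Dendrogram`.
#' @param k number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_dendrogram <- function(dend, k) {
  stats::cutree(dend$hclust, k = k)
}

#' Export a dendrogram as a Newick string
#' @param dend a `Dendrogram`.
#' @param path optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Principal component analysis of samples
#'
#' PCA of the samples in feature space: features are centred (and
#' optionally unit-scaled), and the per-component fraction of total
#' variance is reported — the quantity quoted when two axes are said to
#' explain, e.g., 36% and 30% of the variability between arrays.
#'
#' @param study an `ExpressionStudy`.
#' @param center,scale passed to [stats::prcomp()] (centering on
#'   features; no scaling by default).
#' @return Object of class `PcaResult` with `scores` (samples x
#'   components) and `var_frac` (non-increasing, sums to 1 over the
#'   full rank).
#' @export
pca_study <- function(study, center = TRUE, scale = FALSE) {
  x <- t(study$exprs)
  if (nrow(x) < 2) stop_("need >= 2 samples for PCA")
  tot <- sum(apply(x, 2, stats::var))
  if (tot == 0) stop_("zero-variance data: PCA undefined")
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(x, center = center, scale. = scale)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, var_frac = var_frac,
                 center = center, scale = scale), class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", nrow(x$scores), "samples;",
      "PC1", sprintf("%.1f%%", 100 * x$var_frac[1]),
      if (length(x$var_frac) > 1)
        paste("PC2", sprintf("%.1f%%", 100 * x$var_frac[2])), "\n")
  invisible(x)
}
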