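# Unsupervised structure: most-variant gene selection, per-gene
# standardization, hierarchical clustering with Newick export.

#' Select the most variant genes
#'
#' Returns the `k` genes with the largest sample variance (n - 1
#' denominator) across all samples, computed on the unstandardized values.
#' Ties at the cutoff are broken by gene-id order (C-locale), so the
#' selection is deterministic.
#'
#' @param expression Numeric matrix, genes x samples, with gene row names.
#' @param k Number of genes to keep; must not exceed the gene count.
#' @return Character vector of `k` gene ids in decreasing-variance order.
#' @export
top_variant_genes <- function(expression, k) {
  if (k > nrow(expression))
    stop("k (", k, ") exceeds the number of genes (", nrow(expression), ")",
         call. = FALSE)
  rv <- rowSums((expression - rowMeans(expression))^2) /
    (ncol(expression) - 1)
  ord <- order(-rv, rownames(expression), method = "radix")
  rownames(expression)[ord[seq_len(k)]]
}

#' Standardize each gene to zero mean and unit variance
#'
#' @param expression Numeric matrix, genes x samples. Every gene must have
#'   nonzero variance (filter first, e.g. with [top_variant_genes()]).
#' @return Matrix of the same shape with each row at mean 0, variance 1.
#' @export
standardize <- function(expression) {
  rv <- rowSums((expression - rowMeans(expression))^2) /
    (ncol(expression) - 1)
  if (any(rv == 0))
    stop("zero-variance gene(s) cannot be standardized: ",
         paste(rownames(expression)[rv == 0], collapse = ", "),
         call. = FALSE)
  out <- t(scale(t(expression)))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters the samples (columns) of an expression matrix — Euclidean
#' distance and complete linkage by default — optionally also clustering
#' genes for two-dimensional heat-map display, and optionally cutting the
#' sample tree into a requested number of flat clusters. The sample tree is
#' additionally serialized as Newick text with merge heights, so trees are
#' diffable.
#'
#' @param expression Numeric matrix, genes x samples (at least 2 samples).
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration rule passed to [stats::hclust()] (default
#'   `"complete"`).
#' @param cut_k Optional number of flat clusters to cut the sample tree
#'   into.
#' @param cluster_genes Also cluster the rows (default FALSE).
#' @return A `hier_clustering` list: `samples` (hclust), `newick`
#'   (character), `clusters` (named integer vector or NULL), `genes`
#'   (hclust or NULL).
#' @export
hierarchical_cluster <- function(expression, metric = "euclidean",
                                 linkage = "complete", cut_k = NULL,
                                 cluster_genes = FALSE) {
  if (ncol(expression) < 2L)
    stop("at least 2 samples are required for clustering", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(expression), method = metric),
                      method = linkage)
  clusters <- if (!is.null(cut_k)) stats::cutree(hc, k = cut_k)
  genes <- if (cluster_genes && nrow(expression) >= 2L)
    stats::hclust(stats::dist(expression, method = metric), method = linkage)
  structure(list(samples = hc, newick = cluster_newick(hc),
                 clusters = clusters, genes = genes,
                 metric = metric, linkage = linkage),
            class = "hier_clustering")
}

#' @export
print.hier_clustering <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$samples$labels), "samples (",
      x$metric, "distance,", x$linkage, "linkage )\n")
  if (!is.null(x$clusters))
    cat("  flat clusters:", paste(table(x$clusters), collapse = "/"),
        "samples\n")
  invisible(x)
}

#' Serialize a merge tree as Newick text
#'
#' @param hc An [stats::hclust] object.
#' @return A single Newick string with branch lengths derived from merge
#'   heights.
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Most-variant-gene clustering pipeline
#'
#' The conventional unsupervised view of an expression cohort, in the
#' canonical order: select the top `k_genes` by variance on the raw values,
#' standardize each selected gene to zero mean and unit variance, then
#' cluster the samples hierarchically.
#'
#' @inheritParams hierarchical_cluster
#' @param k_genes Number of most-variant genes to use (500 is the customary
#'   choice for a whole-cohort view; 200 for smaller subsets).
#' @return List: `genes` (selected ids), `standardized` (matrix), and
#'   `clustering` (a `hier_clustering`).
#' @export
explore_structure <- function(expression, k_genes = 500,
                              metric = "euclidean", linkage = "complete",
                              cut_k = NULL, cluster_genes = FALSE) {
  sel <- top_variant_genes(expression, k = min(k_genes, nrow(expression)))
  std <- standardize(expression[sel, , drop = FALSE])
  list(genes = sel, standardized = std,
       clustering = hierarchical_cluster(std, metric = metric,
                                         linkage = linkage, cut_k = cut_k,
                                         cluster_genes = cluster_genes))
}

#' Expression heat map with sample annotation bars
#'
#' Thin wrapper around \pkg{pheatmap} rendering a genes-x-samples heat map
#' with optional per-sample annotation bars (subtype, receptor status,
#' group). Requires the suggested \pkg{pheatmap} package.
#'
#' @param expression Numeric matrix (typically the standardized top-variant
#'   genes).
#' @param annotation Optional data.frame of per-sample annotations, row
#'   names matching the sample ids.
#' @param file Optional output file (png/pdf inferred from extension).
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_heatmap <- function(expression, annotation = NULL, file = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_heatmap() needs the suggested package 'pheatmap'",
         call. = FALSE)
  ph <- pheatmap::pheatmap(expression,
                           annotation_col = annotation,
                           clustering_distance_rows = "euclidean",
                           clustering_distance_cols = "euclidean",
                           clustering_method = "complete",
                           show_rownames = nrow(expression) <= 60,
                           filename = file, ...)
  invisible(ph)
}
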