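# Clustering of binding profiles: 1 - Pearson correlation distance with
# average-linkage (UPGMA) hierarchical clustering, heatmap-ready ordering.

#' Pearson correlation distances between lectin profiles
#'
#' Distance between two lectins is `1 - r` where `r` is the Pearson
#' correlation of their processed combined-Z profiles across glycans
#' (0 for identical profiles, 2 for perfectly anti-correlated ones).
#'
#' @param processed Glycans-by-lectins numeric matrix (columns are
#'   profiles).
#' @return A symmetric matrix of class `dist`-compatible shape (plain
#'   matrix with zero diagonal).
#' @export
pearson_distances <- function(processed) {
  stopifnot(is.matrix(processed))
  if (ncol(processed) < 2L) {
    stop("need >= 2 lectins to compute distances", call. = FALSE)
  }
  sds <- apply(processed, 2L, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    bad <- colnames(processed)[!is.finite(sds) | sds == 0]
    stop("zero-variance profile for lectin(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(processed)
  diag(d) <- 0
  # numerical symmetry is exact for cor(), but enforce it anyway
  (d + t(d)) / 2
}

#' Average-linkage clustering of lectin profiles
#'
#' Standard UPGMA on the `1 - Pearson` distance matrix. Input columns are
#' sorted by lectin id before clustering so merge-order ties are broken
#' lexicographically and the result is independent of input column order.
#'
#' @param dm Distance matrix from [pearson_distances()].
#' @param k Optional number of flat clusters to cut.
#' @return A `lectin_clustering`: the `hclust` tree, the leaf order for
#'   heatmap display, and (if `k` given) a named cluster assignment.
#' @export
average_linkage <- function(dm, k = NULL) {
  stopifnot(is.matrix(dm), identical(rownames(dm), colnames(dm)))
  ord <- order(rownames(dm), method = "radix")
  dm <- dm[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(
    list(hclust = hc, leaf_order = hc$labels[hc$order], k = k,
         clusters = clusters),
    class = "lectin_clustering"
  )
}

#' Cluster lectins (or glycans) by processed binding profile
#'
#' Convenience wrapper: distances via [pearson_distances()] then
#' [average_linkage()]. Set `margin = "glycans"` to cluster the glycan
#' axis of the matrix with identical settings (used for two-way heatmaps).
#'
#' @param processed Glycans-by-lectins processed Z matrix (e.g.
#'   `zs$processed` from [process_scans()]).
#' @param k Optional number of flat clusters.
#' @param margin `"lectins"` (columns, default) or `"glycans"` (rows).
#' @return A `lectin_clustering`.
#' @export
cluster_profiles <- function(processed, k = NULL,
                             margin = c("lectins", "glycans")) {
  margin <- match.arg(margin)
  m <- if (margin == "glycans") t(processed) else processed
  average_linkage(pearson_distances(m), k = k)
}

#' @export
print.lectin_clustering <- function(x, ...) {
  cat("<lectin_clustering> ", length(x$leaf_order), " profiles",
      if (!is.null(x$k)) paste0(", cut at k = ", x$k), "\n", sep = "")
  cat("  leaf order: ", paste(utils::head(x$leaf_order, 8L), collapse = ", "),
      if (length(x$leaf_order) > 8L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Tidy a profile clustering
#' @param x A `lectin_clustering`.
#' @param ... Unused.
#' @return Tibble with `id`, `display_order`, and (when cut) `cluster`.
#' @export
tidy.lectin_clustering <- function(x, ...) {
  out <- tibble::tibble(
    id = x$leaf_order,
    display_order = seq_along(x$leaf_order)
  )
  if (!is.null(x$clusters)) {
    out$cluster <- unname(x$clusters[out$id])
  }
  out
}

#' Export a dendrogram as Newick
#'
#' @param clustering A `lectin_clustering`.
#' @param path Optional file path; when `NULL`, the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
export_newick <- function(clustering, path = NULL) {
  phy <- ape::as.phylo(clustering$hclust)
  if (!is.null(path)) {
    ape::write.tree(phy, file = path)
    return(invisible(ape::write.tree(phy)))
  }
  ape::write.tree(phy)
}

#' Reorder a matrix by dendrogram leaves for heatmap display
#'
#' Returns the matrix with columns (and optionally rows) permuted to the
#' dendrogram leaf order, plus a binary layer thresholded at the binding
#' threshold for the classic bound/unbound overlay.
#'
#' @param processed Glycans-by-lectins matrix.
#' @param lectin_clust A `lectin_clustering` of the columns.
#' @param glycan_clust Optional `lectin_clustering` of the rows.
#' @param threshold Binding threshold for the binary layer.
#' @return List with `matrix` (reordered) and `bound` (0/1 layer).
#' @export
heatmap_export <- function(processed, lectin_clust, glycan_clust = NULL,
                           threshold = binding_threshold()) {
  m <- processed[, lectin_clust$leaf_order, drop = FALSE]
  if (!is.null(glycan_clust)) {
    m <- m[glycan_clust$leaf_order, , drop = FALSE]
  }
  list(matrix = m, bound = (m > threshold) * 1L)
}
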