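# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of processed binding scores
#'
#' Glycans-by-lectins tile plot of background-corrected combined Z-scores,
#' ordered by average-linkage clustering when possible, with bound cells
#' (score above the threshold) outlined.
#'
#' @param object A `zs_result` from [process_scans()].
#' @param cluster Reorder rows/columns by profile clustering (default TRUE
#'   when dimensions allow).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zs_result <- function(object, cluster = TRUE, ...) {
  m <- object$processed
  if (isTRUE(cluster) && ncol(m) >= 3L && nrow(m) >= 3L) {
    lc <- cluster_profiles(m, margin = "lectins")
    gc <- tryCatch(cluster_profiles(m, margin = "glycans"),
                   error = function(e) NULL)
    m <- m[, lc$leaf_order, drop = FALSE]
    if (!is.null(gc)) m <- m[gc$leaf_order, , drop = FALSE]
  }
  df <- tibble::tibble(
    glycan_id = factor(rep(rownames(m), times = ncol(m)),
                       levels = rownames(m)),
    lectin_id = factor(rep(colnames(m), each = nrow(m)),
                       levels = colnames(m)),
    score = as.vector(m)
  )
  df$bound <- df$score >= object$threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lectin_id, y = .data$glycan_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$bound, , drop = FALSE], fill = NA,
                       colour = "yellow", linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "black",
                                  high = "yellow", midpoint = 0,
                                  name = "processed Zs") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Precision/recall ladder of a mined rule set
#'
#' @param object A `lectin_ruleset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lectin_ruleset <- function(object, ...) {
  lv <- object$levels
  if (nrow(lv) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no rule found") +
             ggplot2::theme_void())
  }
  lv$label <- paste0(lv$level, ifelse(is.na(lv$alternative), "",
                                      lv$alternative))
  df <- tidyr::pivot_longer(
    lv[, c("label", "precision", "recall", "estimator_support")],
    cols = c("precision", "recall", "estimator_support"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(0.3, 0.1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "rule level", y = NULL,
                  title = if (!is.na(object$lectin_id)) object$lectin_id,
                  subtitle = paste0("stop: ", object$stop_reason)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Dendrogram of clustered binding profiles
#'
#' @param object A `lectin_clustering`.
#' @param ... Unused.
#' @return A ggplot object (segments of the merge tree).
#' @export
autoplot.lectin_clustering <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # flatten to segments
  segs <- dendrogram_segments(dend)
  labs <- tibble::tibble(x = seq_along(hc$labels),
                         label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02,
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 2.5) +
    ggplot2::scale_y_continuous(name = "1 - Pearson r (average linkage)") +
    ggplot2::scale_x_continuous(name = NULL, breaks = NULL) +
    ggplot2::expand_limits(y = -0.3) +
    ggplot2::theme_minimal()
}

dendrogram_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      return(list(x = attr(node, "x") %||% 0, y = 0))
    }
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    h <- attr(node, "height")
    xs <- vapply(kids, `[[`, numeric(1), "x")
    ys <- vapply(kids, `[[`, numeric(1), "y")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1L]] <<- tibble::tibble(
        x = xs[i], y = ys[i], xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      x = min(xs), y = h, xend = max(xs), yend = h)
    list(x = mean(range(xs)), y = h)
  }
  # assign leaf x positions in dendrogram order
  counter <- 0L
  assign_x <- function(node) {
    if (stats::is.leaf(node)) {
      counter <<- counter + 1L
      attr(node, "x") <- counter
      return(node)
    }
    for (i in seq_along(node)) node[[i]] <- assign_x(node[[i]])
    node
  }
  dend <- assign_x(dend)
  walk(dend)
  dplyr::bind_rows(segs)
}
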