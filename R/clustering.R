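#' @title Hierarchical clustering of the z-scored secretome matrix
#' @name clustering
#' @description
#' For the clustered-heatmap view, each protein row is z-score scaled and
#' rows and columns are clustered agglomeratively (Euclidean distance,
#' average linkage by default). With a batch offset well above the
#' within-batch replicate noise, the top split of the column dendrogram
#' separates the batches.
NULL

#' Z-score scale each row
#'
#' `(x - mean(x)) / sd(x)` per row with the sample SD. Zero-SD rows become
#' rows of zeros (with a warning) rather than NaN.
#'
#' @param m Complete numeric matrix (no missing values).
#' @return Z-scored matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  if (anyNA(m)) stop("zscore_rows expects a complete matrix")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning(sum(zero), " constant row(s) z-scored to zero")
    sd[zero] <- 1
  }
  out <- (m - mu) / sd
  out[zero, ] <- 0
  out
}

#' Agglomerative hierarchical clustering of one axis
#'
#' @param m Complete numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @param metric Distance: `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson r).
#' @param linkage Agglomeration method for [stats::hclust()]: `"average"`
#'   (default), `"complete"`, `"single"`, `"ward.D2"`.
#' @return List with `order` (leaf permutation), `merge`, `height` (the
#'   [stats::hclust()] merge tree), and `labels`. Fewer than 2 items yields
#'   the identity ordering with an empty tree.
#' @export
hier_cluster <- function(m, axis = c("rows", "cols"),
                         metric = c("euclidean", "correlation"),
                         linkage = "average") {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  x <- if (axis == "rows") m else t(m)
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  if (nrow(x) < 2L) {
    return(list(order = seq_len(nrow(x)),
                merge = matrix(integer(0L), 0L, 2L), height = numeric(0L),
                labels = labels, hclust = NULL))
  }
  d <- if (metric == "euclidean") {
    stats::dist(x)
  } else {
    stats::as.dist(1 - stats::cor(t(x)))
  }
  hc <- stats::hclust(d, method = linkage)
  list(order = hc$order, merge = hc$merge, height = hc$height,
       labels = labels, hclust = hc)
}

#' Cluster a matrix on both axes after row z-scoring
#'
#' @param m Complete log-intensity matrix (proteins x samples).
#' @param metric,linkage Passed to [hier_cluster()].
#' @return List of class `cluster_result`: `zscored`, `row_order`,
#'   `col_order`, `row_linkage`, `col_linkage`.
#' @export
cluster_matrix <- function(m, metric = "euclidean", linkage = "average") {
  z <- zscore_rows(m)
  rows <- hier_cluster(z, "rows", metric, linkage)
  cols <- hier_cluster(z, "cols", metric, linkage)
  structure(list(zscored = z,
                 row_order = rows$order, col_order = cols$order,
                 row_linkage = rows, col_linkage = cols),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$zscored), "proteins x",
      ncol(x$zscored), "samples (z-scored rows)\n")
  invisible(x)
}

#' Two-group partition at the top of the column dendrogram
#'
#' @param cr A `cluster_result`.
#' @return Named integer vector (1/2) assigning each sample to one side of
#'   the top column split.
#' @export
top_column_split <- function(cr) {
  stopifnot(inherits(cr, "cluster_result"))
  hc <- cr$col_linkage$hclust
  if (is.null(hc)) stop("fewer than 2 samples: no column dendrogram")
  stats::cutree(hc, k = 2L)
}

#' Export a linkage as a flat merge table
#'
#' One row per internal node: `node_id`, `child_a`, `child_b` (negative =
#' leaf index, positive = earlier node id, the [stats::hclust()] `merge`
#' convention), `height`, `n_leaves`.
#'
#' @param linkage A linkage list from [hier_cluster()].
#' @param path Output TSV path.
#' @export
write_linkage <- function(linkage, path) {
  n_merge <- length(linkage$height)
  n_leaves <- integer(n_merge)
  count <- function(child) if (child < 0L) 1L else n_leaves[child]
  for (i in seq_len(n_merge)) {
    n_leaves[i] <- count(linkage$merge[i, 1L]) + count(linkage$merge[i, 2L])
  }
  utils::write.table(
    data.frame(node_id = seq_len(n_merge),
               child_a = linkage$merge[, 1L], child_b = linkage$merge[, 2L],
               height = linkage$height, n_leaves = n_leaves),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
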