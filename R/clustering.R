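#' Hierarchical clustering of significant features
#'
#' Clusters features (rows) of a log2 CPM matrix after per-row z-scoring,
#' using a correlation (1 - Pearson, default) or Euclidean dissimilarity
#' and average linkage — the common convention for expression heatmaps of
#' significantly regulated miRs. Deterministic given the input order.
#'
#' @param log2_cpm Numeric matrix, features x samples (>= 2 features).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `hclust` (merge table, heights, labels).
#' @export
cluster_features <- function(log2_cpm, distance = c("correlation", "euclidean"),
                             linkage = "average") {
  distance <- match.arg(distance)
  log2_cpm <- as.matrix(log2_cpm)
  if (nrow(log2_cpm) < 2L) stop("need at least two features", call. = FALSE)
  sds <- apply(log2_cpm, 1L, stats::sd)
  if (distance == "correlation" && any(sds == 0))
    stop("constant feature(s) under correlation distance: ",
         paste(rownames(log2_cpm)[sds == 0], collapse = ", "), call. = FALSE)
  z <- (log2_cpm - rowMeans(log2_cpm)) / ifelse(sds > 0, sds, 1)
  d <- if (distance == "correlation")
    stats::as.dist(1 - stats::cor(t(z))) else stats::dist(z)
  stats::hclust(d, method = linkage)
}

#' Sample ordination by leading-logFC multidimensional scaling
#'
#' QC ordination of samples: the distance between two samples is the
#' root-mean-square of their `top_k` largest absolute log2 CPM differences
#' (the "leading log fold change" distance, recomputed per pair), and
#' coordinates come from classical metric scaling (eigendecomposition of
#' the double-centred squared-distance matrix), keeping the top two
#' dimensions. The sign of each dimension is fixed by making its
#' largest-magnitude coordinate positive; replicates of a condition are
#' expected to co-locate.
#'
#' @param log2_cpm Numeric matrix, features x samples (>= 3 samples).
#' @param top_k Number of top differences entering each pairwise distance
#'   (default 500; capped at the number of features).
#' @return An object of class `ordination`: list with `coords` (samples x 2
#'   matrix) and `dist` (symmetric matrix of pairwise distances).
#' @export
sample_ordination <- function(log2_cpm, top_k = 500L) {
  log2_cpm <- as.matrix(log2_cpm)
  ns <- ncol(log2_cpm)
  if (ns < 3L) stop("need at least three samples", call. = FALSE)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  k <- min(as.integer(top_k), nrow(log2_cpm))
  if (is.null(colnames(log2_cpm)))
    colnames(log2_cpm) <- sprintf("sample%02d", seq_len(ns))
  d <- matrix(0, ns, ns, dimnames = list(colnames(log2_cpm), colnames(log2_cpm)))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    dif2 <- (log2_cpm[, i] - log2_cpm[, j])^2
    d[i, j] <- d[j, i] <- sqrt(mean(sort(dif2, decreasing = TRUE)[seq_len(k)]))
  }
  ord <- order(rownames(d))
  cmd <- stats::cmdscale(stats::as.dist(d[ord, ord]), k = 2)
  cmd <- cmd[match(rownames(d), rownames(d)[ord]), , drop = FALSE]
  rownames(cmd) <- rownames(d)
  for (c_ in seq_len(ncol(cmd))) {
    top <- which.max(abs(cmd[, c_]))
    if (cmd[top, c_] < 0) cmd[, c_] <- -cmd[, c_]
  }
  colnames(cmd) <- c("dim1", "dim2")
  structure(list(coords = cmd, dist = d), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, 2 dimensions\n", nrow(x$coords)))
  print(round(x$coords, 3))
  invisible(x)
}

#' @export
plot.ordination <- function(x, col = NULL, ...) {
  plot(x$coords, pch = 16, col = col %||% "black",
       xlab = "dim 1", ylab = "dim 2", ...)
  graphics::text(x$coords, labels = rownames(x$coords), pos = 3, cex = 0.6)
  invisible(x)
}
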