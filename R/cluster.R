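#' Spearman correlation matrix across marker scores
#'
#' Rank-based correlations between markers over patients: symmetric with a
#' unit diagonal. Constant columns have undefined correlations; these are
#' returned as `NA` with a warning naming the markers.
#'
#' @param m patients-by-markers numeric matrix (see [marker_matrix()]);
#'   needs >= 3 patients.
#' @return markers-by-markers correlation matrix.
#' @export
spearman_matrix <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 patients")
  const <- apply(m, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant marker column(s), correlations undefined: ",
            paste(colnames(m)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(r) <- 1
  r
}

#' Hierarchical clustering of patients into prognostic clusters
#'
#' Columns are z-standardized, patients clustered on Euclidean distance with
#' Ward linkage (`ward.D2`) and the tree cut at `k` clusters. Clusters are
#' relabeled `a`, `b`, `c`, ... by descending mean hormone-block score
#' (mean of the available PR/ER/AR/GATA3 columns) so reported labels are
#' stable under permutation of the raw cut labels.
#'
#' @inheritParams spearman_matrix
#' @param k number of clusters (default 3; `2 <= k <=` number of patients).
#' @param hormone_block columns used for the relabeling rule.
#' @return factor of cluster labels (levels `a`, `b`, ...), named by
#'   patient; the `hclust` tree in `attr(, "tree")`.
#' @export
hierarchical_cluster <- function(m, k = 3,
                                 hormone_block = c("PR", "ER", "AR",
                                                   "GATA3")) {
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(m)) stop("k exceeds the number of patients")
  z <- scale(m)
  z[, apply(m, 2, function(v) diff(range(v)) == 0)] <- 0
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  hb <- intersect(hormone_block, colnames(m))
  if (length(hb) == 0L) hb <- colnames(m)[1]
  block_mean <- tapply(rowMeans(m[, hb, drop = FALSE]), raw, mean)
  ord <- order(block_mean, decreasing = TRUE)
  relabel <- stats::setNames(letters[seq_len(k)], names(block_mean)[ord])
  lab <- factor(relabel[as.character(raw)], levels = letters[seq_len(k)])
  names(lab) <- rownames(m)
  attr(lab, "tree") <- hc
  lab
}
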