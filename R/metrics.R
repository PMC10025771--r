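## Clustering evaluation statistics: adjusted Rand index, normalized mutual
## information (arithmetic-mean normalization), maximum-matching supervised
## accuracy, and modularity Q with unweighted edge counts.

.as_labels <- function(x) {
  if (is(x, "SCPartition")) x@labels else as.integer(factor(x))
}

.contingency <- function(pred, truth) {
  table(factor(pred), factor(truth))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions corrected for chance;
#' 1 for identical partitions, about 0 for independent ones, can be
#' negative.
#'
#' @param pred predicted partition (\linkS4class{SCPartition} or label
#'   vector).
#' @param truth reference labels; defaults to the partition's attached
#'   ground truth.
#' @return numeric(1).
#' @export
adjustedRandIndex <- function(pred, truth = NULL) {
  if (is.null(truth) && is(pred, "SCPartition")) truth <- pred@truth
  p <- .as_labels(pred); t <- .as_labels(truth)
  if (length(p) != length(t)) stop("partitions cover different spot sets")
  ct <- .contingency(p, t)
  n <- sum(ct)
  sumij <- sum(choose(ct, 2))
  sumi <- sum(choose(rowSums(ct), 2))
  sumj <- sum(choose(colSums(ct), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)    # both partitions trivial
  (sumij - expected) / (maxidx - expected)
}

#' Normalized mutual information
#'
#' Mutual information of the two partitions over their contingency table,
#' normalized by the arithmetic mean of the two entropies (natural log);
#' lies in [0, 1]. When both partitions are a single cluster the value is
#' defined as 1 with a warning.
#'
#' @inheritParams adjustedRandIndex
#' @return numeric(1).
#' @export
normalizedMutualInfo <- function(pred, truth = NULL) {
  if (is.null(truth) && is(pred, "SCPartition")) truth <- pred@truth
  p <- .as_labels(pred); t <- .as_labels(truth)
  if (length(p) != length(t)) stop("partitions cover different spot sets")
  ct <- .contingency(p, t)
  n <- sum(ct)
  pi_ <- rowSums(ct) / n
  pj <- colSums(ct) / n
  hp <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  ht <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hp + ht == 0) {
    warning("both partitions are a single cluster; NMI defined as 1")
    return(1)
  }
  pij <- ct / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(ct)[nz]] * pj[col(ct)[nz]])))
  2 * mi / (hp + ht)
}

#' Maximum-matching supervised accuracy
#'
#' Maps predicted cluster labels to ground-truth labels by the one-to-one
#' assignment maximizing total overlap (maximum-weight bipartite matching on
#' the contingency table) and reports the matched fraction as a percentage.
#' Invariant under any relabeling of the prediction.
#'
#' @inheritParams adjustedRandIndex
#' @return numeric(1) accuracy in percent.
#' @export
accuracyMaxMatch <- function(pred, truth = NULL) {
  if (is.null(truth) && is(pred, "SCPartition")) truth <- pred@truth
  p <- .as_labels(pred); t <- .as_labels(truth)
  if (length(p) != length(t)) stop("partitions cover different spot sets")
  ct <- as.matrix(.contingency(p, t))
  r <- nrow(ct); c_ <- ncol(ct)
  idx <- which(ct >= 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, r), rep(TRUE, c_)),
    as.vector(t(cbind(idx[, 1], r + idx[, 2]))))
  m <- igraph::max_bipartite_match(
    g, weights = ct[idx] + 1e-9)       # tiny offset keeps zero cells eligible
  matched <- m$matching[seq_len(r)]
  ok <- !is.na(matched)
  100 * sum(ct[cbind(which(ok), matched[ok] - r)]) / length(p)
}

#' Modularity Q of a partition on a network
#'
#' Q = sum_c [ N_inner_c / N_all - ((2 N_inner_c + N_outer_c) / (2 N_all))^2 ]
#' with unweighted edge counts by default (N_inner: edges inside cluster c,
#' N_outer: edges from c to other clusters, N_all: all edges). Lies in
#' [-0.5, 1). With \code{weighted = TRUE}, edge weights replace the counts.
#'
#' @param net a \linkS4class{SimilarityNetwork}.
#' @param partition an \linkS4class{SCPartition} (or label vector) over the
#'   network's spots.
#' @param weighted use edge weights instead of counts.
#' @return numeric(1).
#' @export
modularityQ <- function(net, partition, weighted = FALSE) {
  e <- net@edges[net@edges$w > 0, , drop = FALSE]
  if (!nrow(e)) stop("empty network")
  labs <- .as_labels(partition)
  w <- if (weighted) e$w else rep(1, nrow(e))
  nAll <- sum(w)
  lu <- labs[e$u]; lv <- labs[e$v]
  same <- lu == lv
  inner <- sum(w[same]) / nAll
  # per-cluster endpoint weight: 2*inner_c + outer_c
  deg <- if (weighted) tapply(c(w, w), c(lu, lv), sum) else
    tabulate(c(lu, lv))
  inner - sum((deg / (2 * nAll))^2)
}
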