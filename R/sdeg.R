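## Spatially differentially expressed genes and spatial enrichment.

#' Spatial k-nearest-neighbor adjacency
#'
#' Binary symmetric spot adjacency: N[i, j] = 1 when j is among i's k nearest
#' neighbors in Euclidean pixel coordinates or vice versa; zero diagonal.
#' k = 6 matches the hex geometry of a Visium array.
#'
#' @param x a \linkS4class{SpotExperiment} or a two-column coordinate matrix.
#' @param k neighbors per spot (must be < number of spots).
#' @return a sparse symmetric 0/1 matrix.
#' @export
knnAdjacency <- function(x, k = 6L) {
  pc <- if (is(x, "SpotExperiment")) pixelCoords(x) else x
  n <- nrow(pc)
  stopifnot(k < n)
  d <- as.matrix(stats::dist(pc))
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nb)), x = 1, dims = c(n, n))
  N <- ((N + Matrix::t(N)) > 0) * 1           # symmetrize by OR
  Matrix::diag(N) <- 0
  Matrix::drop0(N)
}

#' Spatial enrichment score of genes
#'
#' The quadratic form x_g' N x_g rewards expression concentrated on mutually
#' adjacent spots; scores are min-max normalized across genes to [0, 1].
#'
#' @param X nonnegative gene x spot matrix (log-normalized layer).
#' @param N spot adjacency from \code{\link{knnAdjacency}}.
#' @param normalize min-max normalize across genes (default TRUE).
#' @return named numeric vector of per-gene scores.
#' @export
enrichmentScore <- function(X, N, normalize = TRUE) {
  X <- as.matrix(X)
  raw <- rowSums(as.matrix(X %*% N) * X)
  names(raw) <- rownames(X)
  if (!normalize) return(raw)
  if (length(raw) == 1L) {
    warning("single gene: normalized enrichment score is degenerate 1")
    return(setNames(1, names(raw)))
  }
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) {
    warning("all enrichment scores equal; returning 1 for every gene")
    return(setNames(rep(1, length(raw)), names(raw)))
  }
  (raw - lo) / (hi - lo)
}

#' Detect spatially differentially expressed genes per cluster
#'
#' For each spatial cluster, every gene is tested by a two-sided Wilcoxon
#' rank-sum test (cluster spots vs. all others; exact for small untied
#' samples, otherwise the normal approximation with tie and continuity
#' correction), p-values are BH-adjusted within the cluster, and genes are
#' ranked by log2 fold change of means, log2((mean_in + eps)/(mean_out +
#' eps)). The top \code{topN} genes per cluster are returned; clusters with
#' fewer than 3 spots are skipped with a warning.
#'
#' @param E log-normalized (raw or enhanced) gene x spot matrix.
#' @param partition an \linkS4class{SCPartition} over the same spots.
#' @param topN genes kept per cluster.
#' @param eps fold-change pseudo-expression.
#' @return a data.frame with columns cluster, gene, log2fc, pvalue, padj,
#'   rank_fc (log2FC order) and rank_p (adjusted-p order).
#' @export
findSDEGs <- function(E, partition, topN = 100L, eps = 1e-9) {
  E <- as.matrix(E)
  if (ncol(E) != length(partition@labels))
    stop("expression matrix and partition cover different spot sets")
  if (partition@nClusters < 2L)
    stop("need at least 2 clusters to contrast")
  genes <- rownames(E)
  if (is.null(genes)) genes <- sprintf("g%06d", seq_len(nrow(E)))
  out <- list()
  for (cl in seq_len(partition@nClusters)) {
    inCl <- partition@labels == cl
    if (sum(inCl) < 3L) {
      warning("cluster ", cl, " has fewer than 3 spots; skipped")
      next
    }
    res <- vapply(seq_len(nrow(E)), function(g) {
      a <- E[g, inCl]; b <- E[g, !inCl]
      p <- if (all(a == a[1]) && all(b == a[1])) 1 else
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      c(log2((mean(a) + eps) / (mean(b) + eps)), p)
    }, numeric(2))
    padj <- stats::p.adjust(res[2, ], method = "BH")
    tab <- data.frame(cluster = cl, gene = genes, log2fc = res[1, ],
                      pvalue = res[2, ], padj = padj)
    tab$rank_fc <- rank(-tab$log2fc, ties.method = "first")
    tab$rank_p <- rank(tab$padj, ties.method = "first")
    tab <- tab[order(tab$rank_fc), , drop = FALSE]
    out[[length(out) + 1L]] <- utils::head(tab, topN)
  }
  if (!length(out)) stop("no cluster had enough spots to test")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
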