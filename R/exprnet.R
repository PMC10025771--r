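## Transcriptomic similarity network.
##
## Counts are depth-normalized and log-transformed, highly variable genes are
## ranked by standardized residual variance around a mean-variance trend, the
## standardized HVG matrix is embedded by PCA, and spots are connected by a
## shared-nearest-neighbor graph whose Jaccard edge weights form the
## transcriptomic similarity network.

#' Log-normalize a count matrix
#'
#' Per spot j: x -> ln(1 + scaleFactor * x / colsum_j). Depth-invariant:
#' doubling every count of a spot leaves its normalized column unchanged.
#'
#' @param counts nonnegative gene x spot matrix (dense or sparse).
#' @param scaleFactor library-size target (default 1e4).
#' @return a matrix of the same class and dimnames.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
  cs <- Matrix::colSums(counts)
  zero <- which(cs == 0)
  if (length(zero))
    stop("all-zero spot(s) cannot be normalized: ",
         paste(utils::head(colnames(counts)[zero], 3), collapse = ", "))
  if (is(counts, "sparseMatrix")) {
    out <- as(as(counts, "generalMatrix"), "CsparseMatrix")
    out@x <- log1p(scaleFactor * out@x / rep.int(cs, diff(out@p)))
    out
  } else {
    log1p(sweep(counts, 2, scaleFactor / cs, "*"))
  }
}

#' Select highly variable genes
#'
#' Genes are ranked by the residual of log10 variance around a loess trend of
#' log10 variance on log10 mean of the log-normalized values (span
#' \code{span}); ties are broken by gene id so the selection is deterministic.
#'
#' @param lognorm log-normalized gene x spot matrix.
#' @param n number of genes to keep (all genes with a warning when n exceeds
#'   the gene count).
#' @param span loess span of the mean-variance trend.
#' @return integer vector of row indices, ordered most to least variable.
#' @export
selectHVG <- function(lognorm, n = 2000L, span = 0.3) {
  G <- nrow(lognorm)
  if (n >= G) {
    if (n > G) warning("n exceeds the gene count; returning all genes")
    n <- G
  }
  mu <- Matrix::rowMeans(lognorm)
  ex2 <- Matrix::rowMeans(lognorm^2)
  va <- pmax(0, ex2 - mu^2) * ncol(lognorm) / max(1, ncol(lognorm) - 1)
  ids <- rownames(lognorm)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_len(G))
  usable <- which(va > 0 & mu > 0)
  resid <- rep(-Inf, G)
  if (length(usable) >= 5L) {
    lm_ <- log10(mu[usable]); lv <- log10(va[usable])
    # a local fit needs enough genes to be stable; fall back to a straight
    # line on small panels
    fit <- if (length(usable) >= 30L) {
      tryCatch(
        suppressWarnings(
          stats::loess(lv ~ lm_, span = span, degree = 2,
                       control = stats::loess.control(surface = "direct"))),
        error = function(e) stats::lm(lv ~ lm_))
    } else {
      stats::lm(lv ~ lm_)
    }
    resid[usable] <- lv - suppressWarnings(stats::fitted(fit))
  } else {
    resid[usable] <- log10(va[usable])
  }
  ord <- order(-resid, ids)
  ord[seq_len(n)]
}

#' Standardize genes across spots
#'
#' Centers and scales each gene to unit variance; standardized values are
#' clipped at \code{+/- clip} (set \code{clip = Inf} to disable). Genes with
#' zero variance become all-zero rows.
#'
#' @param lognorm gene x spot matrix (typically the HVG subset).
#' @param clip clipping bound for standardized values.
#' @return a dense gene x spot matrix.
#' @export
scaleGenes <- function(lognorm, clip = 10) {
  m <- as.matrix(lognorm)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sdv[sdv == 0] <- Inf
  z <- (m - mu) / sdv
  if (is.finite(clip)) z <- pmin(pmax(z, -clip), clip)
  z
}

#' PCA embedding of spots
#'
#' Singular value decomposition of the spot x gene standardized matrix after
#' column centering. Component signs are fixed by making the
#' largest-magnitude gene loading of each component positive, so the
#' embedding is fully deterministic.
#'
#' @param scaled gene x spot standardized matrix.
#' @param nPCs number of components (reduced with a warning when larger than
#'   the matrix rank allows).
#' @return spots x nPCs matrix of principal component scores.
#' @export
pcaEmbed <- function(scaled, nPCs = 50L) {
  X <- t(as.matrix(scaled))                       # spots x genes
  X <- sweep(X, 2, colMeans(X))
  maxPC <- min(dim(X)) - 1L
  if (nPCs > maxPC) {
    warning("nPCs reduced from ", nPCs, " to ", maxPC)
    nPCs <- maxPC
  }
  sv <- svd(X, nu = nPCs, nv = nPCs)
  flip <- vapply(seq_len(nPCs), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u[, seq_len(nPCs), drop = FALSE] %*%
    diag(sv$d[seq_len(nPCs)], nPCs) %*% diag(flip, nPCs)
  rownames(scores) <- colnames(scaled)
  colnames(scores) <- paste0("PC", seq_len(nPCs))
  scores
}

#' Shared-nearest-neighbor graph
#'
#' Each spot's k nearest Euclidean neighbors in PC space (self included)
#' define a neighbor set; the edge weight between two spots is the Jaccard
#' overlap of their sets, with weights at or below \code{prune} removed.
#'
#' @param pcs spots x d embedding (rownames = barcodes).
#' @param k neighborhood size (reduced with a warning when >= the spot count).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return A \linkS4class{SimilarityNetwork} with role "T".
#' @export
snnGraph <- function(pcs, k = 20L, prune = 1 / 15) {
  n <- nrow(pcs)
  if (k >= n) {
    warning("k reduced from ", k, " to ", n - 1L)
    k <- n - 1L
  }
  d <- as.matrix(stats::dist(pcs))
  # neighbor sets include the spot itself
  nb <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nb)), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(A)                 # |N(u) intersect N(v)|
  shared <- as(Matrix::triu(shared, k = 1), "TsparseMatrix")
  jac <- shared@x / (2 * k - shared@x)
  keep <- jac > prune
  SimilarityNetwork(
    data.frame(u = shared@i[keep] + 1L, v = shared@j[keep] + 1L,
               w = jac[keep]),
    barcodes = rownames(pcs), role = "T")
}

#' Transcriptomic network from raw counts
#'
#' Convenience pipeline: log-normalize, select HVGs, standardize, embed with
#' PCA, and build the SNN graph.
#'
#' @param counts gene x spot count matrix.
#' @param nHVG,nPCs,k,prune,scaleFactor,clip see the individual steps.
#' @return a list with elements \code{lognorm}, \code{hvg}, \code{pcs} and
#'   \code{network} (role "T").
#' @export
exprNetwork <- function(counts, nHVG = 2000L, nPCs = 50L, k = 20L,
                        prune = 1 / 15, scaleFactor = 1e4, clip = 10) {
  ln <- logNormalize(counts, scaleFactor)
  hvg <- selectHVG(ln, nHVG)
  sc <- scaleGenes(ln[hvg, , drop = FALSE], clip = clip)
  pcs <- pcaEmbed(sc, nPCs)
  list(lognorm = ln, hvg = hvg, pcs = pcs,
       network = snnGraph(pcs, k = k, prune = prune))
}
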