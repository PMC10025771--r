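## Fusing the histological (H), transcriptomic (T) and spatial modalities.
##
## Every candidate spot pair (u, v) receives the fused weight
## S = (H + T * I(T > 0)) / (2 * A), where A is the Manhattan distance in
## array coordinates; S is then min-max normalized to [0, 1]. Candidate pairs
## are the immediate spatial neighbors (array distance <= aMax, which covers
## the 6 hex neighbors of a Visium spot at aMax = 2) united with all SNN
## edges; the 1/A factor makes omitted distant pairs negligible, and a dense
## all-pairs mode is available for validation on small samples.

#' Manhattan distance between spots in array coordinates
#'
#' @param x a \linkS4class{SpotExperiment} (or a two-column array-coordinate
#'   matrix).
#' @param u,v spot indices; vectorized, recycled to equal length.
#' @return numeric vector of |row_u - row_v| + |col_u - col_v|.
#' @export
manhattanDistance <- function(x, u, v) {
  if (any(u == v)) stop("Manhattan distance requested for a spot with itself")
  ac <- if (is(x, "SpotExperiment")) arrayCoords(x) else x
  abs(ac[u, 1] - ac[v, 1]) + abs(ac[u, 2] - ac[v, 2])
}

#' Candidate spot pairs for network fusion
#'
#' The union of (i) all pairs at Manhattan array distance <= \code{aMax} and
#' (ii) all pairs carrying a nonzero transcriptomic edge. \code{aMax = Inf}
#' yields all pairs (dense mode); \code{aMax = 0} yields only the T edges.
#'
#' @param x a \linkS4class{SpotExperiment} or array-coordinate matrix whose
#'   rows are the spots under consideration.
#' @param tNet optional \linkS4class{SimilarityNetwork} with role "T" over the
#'   same spots.
#' @param aMax spatial cutoff in array units.
#' @return data.frame with integer columns u < v.
#' @export
candidatePairs <- function(x, tNet = NULL, aMax = 2) {
  ac <- if (is(x, "SpotExperiment")) arrayCoords(x) else x
  n <- nrow(ac)
  pairs <- NULL
  if (aMax > 0) {
    if (is.infinite(aMax)) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pairs <- data.frame(u = idx[, 1], v = idx[, 2])
    } else {
      d <- as.matrix(stats::dist(ac, method = "manhattan"))
      idx <- which(upper.tri(d) & d <= aMax, arr.ind = TRUE)
      pairs <- data.frame(u = idx[, 1], v = idx[, 2])
    }
  }
  if (!is.null(tNet) && nrow(tNet@edges)) {
    te <- tNet@edges[tNet@edges$w > 0, c("u", "v")]
    pairs <- if (is.null(pairs)) te else unique(rbind(pairs, te))
  }
  if (is.null(pairs)) pairs <- data.frame(u = integer(0), v = integer(0))
  pairs <- pairs[order(pairs$u, pairs$v), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

.edge_key <- function(u, v, n) (pmin(u, v) - 1) * n + pmax(u, v)

#' Fuse the modality networks
#'
#' Computes S = (H + T) / (2 * A) over the candidate pairs, where T is taken
#' as 0 on pairs without a transcriptomic edge (the indicator in the fusion
#' rule) and A is the Manhattan array distance. Every candidate pair must
#' carry an H value.
#'
#' @param hNet \linkS4class{SimilarityNetwork} with role "H" covering all
#'   \code{pairs}.
#' @param tNet \linkS4class{SimilarityNetwork} with role "T" (may be NULL).
#' @param x a \linkS4class{SpotExperiment} or array-coordinate matrix.
#' @param pairs data.frame of candidate pairs from
#'   \code{\link{candidatePairs}}.
#' @return A \linkS4class{SimilarityNetwork} with role "S".
#' @export
fuseNetworks <- function(hNet, tNet, x, pairs) {
  n <- hNet@nSpots
  key <- .edge_key(pairs$u, pairs$v, n)
  hkey <- .edge_key(hNet@edges$u, hNet@edges$v, n)
  hpos <- match(key, hkey)
  if (anyNA(hpos))
    stop(sum(is.na(hpos)), " candidate pair(s) lack a histological weight")
  hval <- hNet@edges$w[hpos]
  tval <- numeric(nrow(pairs))
  if (!is.null(tNet) && nrow(tNet@edges)) {
    tkey <- .edge_key(tNet@edges$u, tNet@edges$v, n)
    tpos <- match(key, tkey)
    tval[!is.na(tpos)] <- tNet@edges$w[tpos[!is.na(tpos)]]
  }
  A <- manhattanDistance(x, pairs$u, pairs$v)
  SimilarityNetwork(data.frame(u = pairs$u, v = pairs$v,
                               w = (hval + tval) / (2 * A)),
                    barcodes = hNet@barcodes, role = "S")
}

#' Min-max normalize a fused network
#'
#' Rescales the stored edge weights to [0, 1] by (w - min) / (max - min),
#' taken over stored edges only; edges whose normalized weight is 0 are
#' dropped. If all weights are equal every edge gets weight 1 with a warning.
#'
#' @param net a \linkS4class{SimilarityNetwork} (role "S").
#' @return A \linkS4class{SimilarityNetwork} with role "Sstar".
#' @export
minmaxNormalize <- function(net) {
  w <- net@edges$w
  if (!length(w)) stop("cannot normalize an empty network")
  lo <- min(w); hi <- max(w)
  if (hi == lo) {
    warning("all fused weights equal; setting every edge weight to 1")
    wn <- rep(1, length(w))
  } else {
    wn <- (w - lo) / (hi - lo)
  }
  e <- data.frame(u = net@edges$u, v = net@edges$v, w = wn)
  e <- e[e$w > 0, , drop = FALSE]
  SimilarityNetwork(e, barcodes = net@barcodes, role = "Sstar")
}
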