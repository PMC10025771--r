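## End-to-end convenience wrappers: build the three modality networks, fuse
## them, cluster, and enhance.

#' Build the fused multimodal network for a sample
#'
#' Runs the full network construction: grayscale + foreground segmentation of
#' the attached image, MRF pixel clustering, spot label distributions and the
#' histological network H; log-normalization, HVG selection, PCA and the SNN
#' transcriptomic network T; candidate pairs (immediate spatial neighbors
#' united with T edges, or all pairs in dense mode), fusion
#' S = (H + T) / (2A), and min-max normalization. Off-tissue spots are
#' excluded by default.
#'
#' @param x a \linkS4class{SpotExperiment} with an image attached.
#' @param K,beta,neighborhood,mrfMaxIter,maxSide MRF parameters
#'   (\code{\link{mrfSegment}}).
#' @param nHVG,nPCs,k,prune transcriptomic parameters
#'   (\code{\link{exprNetwork}}).
#' @param aMax spatial candidate cutoff; \code{Inf} for dense all-pairs
#'   fusion.
#' @param includeOffTissue keep off-tissue spots in the networks.
#' @param seed seed for the MRF initialization.
#' @return a list: \code{spots} (integer index of the spots used),
#'   \code{lognorm} (log-normalized matrix on those spots), \code{labelDist},
#'   \code{hNet}, \code{tNet}, \code{fused} (role "S"), and \code{network}
#'   (the normalized "Sstar" network).
#' @export
buildFusedNetwork <- function(x, K = 50L, beta = 1.0, neighborhood = 8L,
                              mrfMaxIter = 30L, maxSide = 2000L,
                              nHVG = 2000L, nPCs = 50L, k = 20L,
                              prune = 1 / 15, aMax = 2,
                              includeOffTissue = FALSE, seed = 1L) {
  stopifnot(is(x, "SpotExperiment"))
  if (is.null(histoImage(x)))
    stop("no image attached; the fused network needs the histology modality")
  spots <- if (includeOffTissue) seq_len(ncol(x)) else which(inTissue(x))
  cs <- Matrix::colSums(SummarizedExperiment::assay(x, "counts")[, spots])
  if (any(cs == 0)) {
    warning(sum(cs == 0), " spot(s) without counts dropped")
    spots <- spots[cs > 0]
  }
  xs <- x[, spots]
  img <- foregroundMask(histoImage(xs))
  field <- mrfSegment(img, K = K, beta = beta, neighborhood = neighborhood,
                      maxIter = mrfMaxIter, maxSide = maxSide, seed = seed)
  w <- spotLabelDistribution(field, xs)
  expr <- exprNetwork(SummarizedExperiment::assay(xs, "counts"),
                      nHVG = nHVG, nPCs = nPCs, k = k, prune = prune)
  pairs <- candidatePairs(xs, expr$network, aMax = aMax)
  hNet <- histoNetwork(w, pairs)
  fused <- fuseNetworks(hNet, expr$network, xs, pairs)
  list(spots = spots, lognorm = expr$lognorm, labelDist = w,
       field = field, hNet = hNet, tNet = expr$network, fused = fused,
       network = minmaxNormalize(fused))
}

#' Cluster a sample into spatial clusters
#'
#' Builds the fused network (\code{\link{buildFusedNetwork}}) and partitions
#' it by random-walk agglomeration (\code{\link{walktrapCluster}}). Planted
#' or annotated region labels found in \code{metadata(x)$region} are attached
#' to the partition as ground truth.
#'
#' @param x a \linkS4class{SpotExperiment}.
#' @param nClusters optional fixed cluster count; the default cuts at
#'   maximum modularity.
#' @param t random-walk step count.
#' @param minSize smallest admissible cluster.
#' @param ... forwarded to \code{\link{buildFusedNetwork}}.
#' @return a list: \code{partition} (an \linkS4class{SCPartition} with
#'   ground truth when available) plus everything
#'   \code{\link{buildFusedNetwork}} returns.
#' @export
clusterSpots <- function(x, nClusters = NULL, t = 4L, minSize = 5L, ...) {
  net <- buildFusedNetwork(x, ...)
  xs <- x[, net$spots]
  part <- walktrapCluster(net$network, t = t, nClusters = nClusters,
                          minSize = minSize, coords = arrayCoords(xs))
  truth <- S4Vectors::metadata(x)$region
  if (!is.null(truth)) {
    tr <- truth[net$spots]
    if (!anyNA(tr)) {
      q <- attr(part, "Q")
      part <- SCPartition(part@labels, part@barcodes, method = part@method,
                          truth = tr)
      attr(part, "Q") <- q
    }
  }
  c(list(partition = part), net)
}
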