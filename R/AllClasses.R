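#' @import methods
#' @importFrom stats setNames
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Grayscale histology image
#'
#' Container for a single-channel brightfield image: an intensity matrix laid
#' out like the image (rows = image rows), an optional logical foreground mask
#' of the same shape, and the intensity ceiling (255 for 8-bit input, 1 for
#' unit-range input) so downstream code knows which scale the values are on.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot foreground logical matrix of the same shape, or NULL if not yet set.
#' @slot maxval numeric(1), the nominal intensity ceiling (1 or 255).
#'
#' @exportClass HistoImage
setClass("HistoImage",
  representation(pixels = "matrix", foreground = "matrixOrNULL",
                 maxval = "numeric"),
  prototype(foreground = NULL, maxval = 255)
)

setValidity("HistoImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  if (!is.null(object@foreground) &&
      !identical(dim(object@foreground), dim(object@pixels)))
    msg <- c(msg, "'foreground' must have the same shape as 'pixels'")
  if (length(object@maxval) != 1L || object@maxval <= 0)
    msg <- c(msg, "'maxval' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Spot-level spatial transcriptomics experiment
#'
#' Extends \linkS4class{SingleCellExperiment}: columns are spots, the
#' \code{counts} assay holds the gene x spot UMI matrix, and \code{colData}
#' carries the spot geometry (\code{in_tissue}, \code{array_row},
#' \code{array_col}, \code{pxl_row}, \code{pxl_col}). Pixel coordinates are
#' (row, col), 0-based, in the coordinate frame of the attached image. The
#' matched histology image, when available, lives in the \code{image} slot.
#'
#' @slot image a \linkS4class{HistoImage} or NULL.
#' @slot spotDiameter numeric(1), spot diameter in image pixels.
#'
#' @exportClass SpotExperiment
setClass("SpotExperiment",
  contains = "SingleCellExperiment",
  representation(image = "ANY", spotDiameter = "numeric"),
  prototype(image = NULL, spotDiameter = NA_real_)
)

.spot_cols <- c("in_tissue", "array_row", "array_col", "pxl_row", "pxl_col")

setValidity("SpotExperiment", function(object) {
  msg <- NULL
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.spot_cols, colnames(cd))
  if (length(missing_cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "spot barcodes must be unique")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else if (min(SummarizedExperiment::assay(object, "counts")) < 0)
    msg <- c(msg, "counts must be nonnegative")
  if (!is.null(object@image)) {
    if (!is(object@image, "HistoImage"))
      msg <- c(msg, "'image' must be a HistoImage or NULL")
    else if (!length(missing_cols)) {
      img <- object@image
      it <- as.logical(cd$in_tissue)
      r <- cd$pxl_row[it]; cc <- cd$pxl_col[it]
      if (length(r) && (any(r < 0 | r > nrow(img@pixels) - 1) ||
                        any(cc < 0 | cc > ncol(img@pixels) - 1)))
        msg <- c(msg, "in-tissue spot pixel coordinates fall outside the image")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Pixel label field from MRF segmentation
#'
#' Per-pixel hidden labels over the image foreground: 0 marks background,
#' 1..K a pixel cluster. Gaussian emission parameters and the smoothness
#' weight used to obtain the field are kept for inspection.
#'
#' @slot labels integer matrix, image-shaped; 0 on background.
#' @slot K integer(1), number of pixel clusters.
#' @slot clusterMeans,clusterVars numeric(K) Gaussian emission parameters.
#' @slot beta numeric(1), Potts pairwise smoothness weight (>= 0).
#' @slot nIter integer(1), sweeps actually run.
#'
#' @exportClass PixelLabelField
setClass("PixelLabelField",
  representation(labels = "matrix", K = "integer", clusterMeans = "numeric",
                 clusterVars = "numeric", beta = "numeric", nIter = "integer")
)

setValidity("PixelLabelField", function(object) {
  msg <- NULL
  lab <- object@labels
  if (object@K < 2L) msg <- c(msg, "K must be >= 2")
  if (any(lab < 0L) || any(lab > object@K))
    msg <- c(msg, "labels must lie in 0..K")
  if (length(object@clusterMeans) != object@K ||
      length(object@clusterVars) != object@K)
    msg <- c(msg, "emission parameter vectors must have length K")
  if (any(object@clusterVars <= 0)) msg <- c(msg, "cluster variances must be > 0")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Weighted spot-spot similarity network
#'
#' A symmetric weighted graph over the spots of one sample, stored as an edge
#' list with one row per unordered pair (u < v, integer spot indices into
#' \code{barcodes}). The \code{role} records which network this is:
#' histological ("H"), transcriptomic ("T"), spatial-distance ("A"), fused
#' ("S"), or min-max normalized fused ("Sstar").
#'
#' @slot nSpots integer(1).
#' @slot barcodes character vector naming the spots.
#' @slot edges data.frame with integer columns u, v and numeric w.
#' @slot role character(1), one of H, T, A, S, Sstar.
#'
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork",
  representation(nSpots = "integer", barcodes = "character",
                 edges = "data.frame", role = "character")
)

setValidity("SimilarityNetwork", function(object) {
  msg <- NULL
  e <- object@edges
  if (!all(c("u", "v", "w") %in% colnames(e)))
    msg <- c(msg, "edges must have columns u, v, w")
  else {
    if (nrow(e)) {
      if (any(e$u >= e$v)) msg <- c(msg, "edges must satisfy u < v (no self-edges)")
      if (any(e$u < 1L) || any(e$v > object@nSpots))
        msg <- c(msg, "edge endpoints out of range")
      if (any(e$w < 0)) msg <- c(msg, "edge weights must be >= 0")
      if (object@role == "Sstar" && any(e$w > 1 + 1e-12))
        msg <- c(msg, "normalized network weights must lie in [0, 1]")
    }
  }
  if (length(object@barcodes) != object@nSpots)
    msg <- c(msg, "barcodes length must equal nSpots")
  if (!object@role %in% c("H", "T", "A", "S", "Sstar"))
    msg <- c(msg, "role must be one of H, T, A, S, Sstar")
  if (is.null(msg)) TRUE else msg
})

#' Spatial cluster partition
#'
#' Spot-to-cluster assignment over a fixed barcode set, with labels contiguous
#' from 1 and an optional planted/annotated ground truth alongside.
#'
#' @slot labels integer vector, one label in 1..nClusters per spot.
#' @slot barcodes character vector of the spots labeled.
#' @slot nClusters integer(1).
#' @slot method character(1) free-text provenance.
#' @slot truth optional integer vector of ground-truth labels (or NULL).
#'
#' @exportClass SCPartition
setClass("SCPartition",
  representation(labels = "integer", barcodes = "character",
                 nClusters = "integer", method = "character",
                 truth = "integerOrNULL"),
  prototype(truth = NULL, method = "unknown")
)

setValidity("SCPartition", function(object) {
  msg <- NULL
  if (length(object@labels) != length(object@barcodes))
    msg <- c(msg, "labels and barcodes must have equal length")
  if (length(object@labels)) {
    if (any(object@labels < 1L) || any(object@labels > object@nClusters))
      msg <- c(msg, "labels must lie in 1..nClusters")
    if (!all(seq_len(object@nClusters) %in% object@labels))
      msg <- c(msg, "labels must be contiguous from 1 (every cluster non-empty)")
  }
  if (!is.null(object@truth) && length(object@truth) != length(object@labels))
    msg <- c(msg, "truth must match labels in length")
  if (is.null(msg)) TRUE else msg
})

#' Noise-simulation configuration
#'
#' Parameters of the two sequencing-ST noise processes: permeabilization
#' diffusion (rate \code{phi}, Gaussian kernel scales \code{sigma1},
#' \code{sigma2} and correlation \code{rho}) and dropout (\code{dropoutRate},
#' the fraction of expression-matrix entries zeroed). \code{rho} is clamped to
#' |rho| <= 0.99 so the kernel covariance stays positive definite.
#'
#' @slot phi numeric(1) in [0, 1), diffusion rate.
#' @slot sigma1,sigma2 numeric(1) > 0, kernel scales in array units.
#' @slot rho numeric(1), kernel correlation, |rho| <= 0.99.
#' @slot dropoutRate numeric(1) in [0, 1).
#' @slot seed integer(1) RNG seed.
#'
#' @exportClass NoiseConfig
setClass("NoiseConfig",
  representation(phi = "numeric", sigma1 = "numeric", sigma2 = "numeric",
                 rho = "numeric", dropoutRate = "numeric", seed = "integer"),
  prototype(phi = 0, sigma1 = 4, sigma2 = 4, rho = 0, dropoutRate = 0,
            seed = 1L)
)

setValidity("NoiseConfig", function(object) {
  msg <- NULL
  if (object@phi < 0 || object@phi >= 1) msg <- c(msg, "phi must lie in [0, 1)")
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    msg <- c(msg, "sigma1 and sigma2 must be > 0")
  if (abs(object@rho) > 0.99)
    msg <- c(msg, "|rho| must be <= 0.99 (rho = 1 makes the kernel singular)")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic tissue specification
#'
#' Describes a self-contained Visium-like fixture: a hex (Visium parity) or
#' square spot grid with an off-tissue margin, a region map (Voronoi cells of
#' seeded centers), a textured grayscale image whose per-region intensity
#' distributions overlap, and a count model (negative-binomial per-spot depth,
#' Poisson sampling, region marker genes over a flat background).
#'
#' @slot nRows,nCols integer grid dimensions (spots).
#' @slot grid character(1), "hex" or "square".
#' @slot nRegions integer(1) number of planted regions.
#' @slot nGenes integer(1) total genes; the first
#'   \code{nRegions * markersPerRegion} are region markers.
#' @slot markersPerRegion integer(1).
#' @slot markerMean numeric(1) mean count of a marker in its home region.
#' @slot backgroundMean numeric(1) mean count of every gene elsewhere.
#' @slot depthSize,depthMean numeric(1) negative-binomial size and mean of the
#'   per-spot library-size factor (factor = depth / depthMean).
#' @slot imageMeans numeric(nRegions) per-region image intensity means (0-255).
#' @slot imageSd numeric(1) image noise standard deviation.
#' @slot marginSpots integer(1) width of the off-tissue spot margin.
#' @slot seed integer(1).
#'
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nRows = "integer", nCols = "integer", grid = "character",
                 nRegions = "integer", nGenes = "integer",
                 markersPerRegion = "integer", markerMean = "numeric",
                 backgroundMean = "numeric", depthSize = "numeric",
                 depthMean = "numeric", imageMeans = "numeric",
                 imageSd = "numeric", marginSpots = "integer",
                 seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (!object@grid %in% c("hex", "square")) msg <- c(msg, "grid must be 'hex' or 'square'")
  if (length(object@imageMeans) != object@nRegions)
    msg <- c(msg, "imageMeans must have one entry per region")
  if (object@markerMean <= object@backgroundMean)
    msg <- c(msg, "markerMean must exceed backgroundMean")
  if (object@nGenes < object@nRegions * object@markersPerRegion)
    msg <- c(msg, "nGenes too small for the requested markers")
  if (is.null(msg)) TRUE else msg
})
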