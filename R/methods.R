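#' Construct a SpotExperiment
#'
#' @param counts gene x spot matrix (dense or sparse) of nonnegative counts.
#' @param positions data.frame with columns \code{barcode}, \code{in_tissue},
#'   \code{array_row}, \code{array_col}, \code{pxl_row}, \code{pxl_col}; row
#'   order defines spot order.
#' @param geneIds character vector of gene identifiers (defaults to the
#'   rownames of \code{counts}).
#' @param image optional \linkS4class{HistoImage}.
#' @param spotDiameter spot diameter in image pixels.
#'
#' @return A \linkS4class{SpotExperiment}.
#' @export
SpotExperiment <- function(counts, positions, geneIds = rownames(counts),
                           image = NULL, spotDiameter = NA_real_) {
  stopifnot(is.data.frame(positions),
            all(c("barcode", .spot_cols) %in% colnames(positions)))
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (ncol(counts) != nrow(positions))
    stop("counts has ", ncol(counts), " columns but positions describes ",
         nrow(positions), " spots")
  if (is.null(geneIds)) geneIds <- sprintf("gene%04d", seq_len(nrow(counts)))
  rownames(counts) <- geneIds
  colnames(counts) <- positions$barcode
  cd <- S4Vectors::DataFrame(positions[, .spot_cols, drop = FALSE],
                             row.names = positions$barcode)
  cd$in_tissue <- as.logical(cd$in_tissue)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  new("SpotExperiment", sce, image = image, spotDiameter = spotDiameter)
}

#' Construct a HistoImage
#'
#' @param pixels numeric intensity matrix (or a height x width x 3 RGB array,
#'   converted with \code{\link{toGrayscale}}).
#' @param foreground optional logical mask of the same shape.
#' @param maxval intensity ceiling, 255 (8-bit) or 1 (unit range).
#' @return A \linkS4class{HistoImage}.
#' @export
HistoImage <- function(pixels, foreground = NULL, maxval = 255) {
  if (length(dim(pixels)) == 3L) return(toGrayscale(pixels, maxval = maxval))
  new("HistoImage", pixels = pixels, foreground = foreground, maxval = maxval)
}

#' Construct a SimilarityNetwork
#'
#' @param edges data.frame with columns u, v (integer spot indices) and w
#'   (nonnegative weight); pairs are stored unordered with u < v and
#'   duplicate pairs are an error.
#' @param barcodes character vector naming the spots.
#' @param role one of "H", "T", "A", "S", "Sstar".
#' @return A \linkS4class{SimilarityNetwork}.
#' @export
SimilarityNetwork <- function(edges, barcodes, role) {
  edges <- data.frame(u = as.integer(pmin(edges$u, edges$v)),
                      v = as.integer(pmax(edges$u, edges$v)),
                      w = as.numeric(edges$w))
  if (anyDuplicated(edges[, c("u", "v")]))
    stop("duplicate edges in network edge list")
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  new("SimilarityNetwork", nSpots = length(barcodes),
      barcodes = as.character(barcodes), edges = edges, role = role)
}

#' Construct an SCPartition
#'
#' Labels are relabeled to contiguous integers 1..k preserving first-appearance
#' order, so arbitrary label vectors (factors, characters) are accepted.
#'
#' @param labels cluster assignment, one per barcode.
#' @param barcodes character vector of spot barcodes.
#' @param method free-text provenance string.
#' @param truth optional ground-truth labels.
#' @return An \linkS4class{SCPartition}.
#' @export
SCPartition <- function(labels, barcodes, method = "unknown", truth = NULL) {
  lab <- as.integer(factor(labels, levels = unique(labels)))
  tr <- if (is.null(truth)) NULL else
    as.integer(factor(truth, levels = unique(truth)))
  new("SCPartition", labels = lab, barcodes = as.character(barcodes),
      nClusters = length(unique(lab)), method = method, truth = tr)
}

#' Construct a NoiseConfig
#'
#' @param phi diffusion rate in [0, 1).
#' @param sigma1,sigma2 Gaussian kernel scales (array units); default 4.
#' @param rho kernel correlation; clamped to |rho| <= 0.99.
#' @param dropoutRate fraction of matrix entries zeroed, in [0, 1).
#' @param seed RNG seed.
#' @return A \linkS4class{NoiseConfig}.
#' @export
NoiseConfig <- function(phi = 0, sigma1 = 4, sigma2 = 4, rho = 0,
                        dropoutRate = 0, seed = 1L) {
  if (abs(rho) > 0.99) {
    warning("rho clamped to +/-0.99 to keep the kernel covariance invertible")
    rho <- sign(rho) * 0.99
  }
  new("NoiseConfig", phi = phi, sigma1 = sigma1, sigma2 = sigma2, rho = rho,
      dropoutRate = dropoutRate, seed = as.integer(seed))
}

## ---- accessors -------------------------------------------------------------

#' Accessors for SpotExperiment
#'
#' \code{arrayCoords} and \code{pixelCoords} return two-column matrices
#' (row, col) in array and image-pixel coordinates; \code{inTissue} the
#' logical tissue flag; \code{histoImage} the attached image;
#' \code{spotDiameter} the spot diameter in pixels.
#'
#' @param x a \linkS4class{SpotExperiment}.
#' @param value replacement \linkS4class{HistoImage}.
#' @name SpotExperiment-accessors
NULL

#' @rdname SpotExperiment-accessors
#' @export
setMethod("arrayCoords", "SpotExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(row = cd$array_row, col = cd$array_col)
  rownames(m) <- colnames(x)
  m
})

#' @rdname SpotExperiment-accessors
#' @export
setMethod("pixelCoords", "SpotExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(row = cd$pxl_row, col = cd$pxl_col)
  rownames(m) <- colnames(x)
  m
})

#' @rdname SpotExperiment-accessors
#' @export
setMethod("inTissue", "SpotExperiment", function(x)
  setNames(as.logical(SummarizedExperiment::colData(x)$in_tissue), colnames(x)))

#' @rdname SpotExperiment-accessors
#' @export
setMethod("histoImage", "SpotExperiment", function(x) x@image)

#' @rdname SpotExperiment-accessors
#' @export
setMethod("histoImage<-", "SpotExperiment", function(x, value) {
  x@image <- value
  validObject(x)
  x
})

#' @rdname SpotExperiment-accessors
#' @export
setMethod("spotDiameter", "SpotExperiment", function(x) x@spotDiameter)

#' Accessors for SimilarityNetwork
#'
#' @param x a \linkS4class{SimilarityNetwork}.
#' @name SimilarityNetwork-accessors
NULL

#' @rdname SimilarityNetwork-accessors
#' @export
setMethod("networkEdges", "SimilarityNetwork", function(x) x@edges)

#' @rdname SimilarityNetwork-accessors
#' @export
setMethod("networkRole", "SimilarityNetwork", function(x) x@role)

#' Accessors for SCPartition
#'
#' @param x an \linkS4class{SCPartition}.
#' @name SCPartition-accessors
NULL

#' @rdname SCPartition-accessors
#' @export
setMethod("clusterLabels", "SCPartition", function(x)
  setNames(x@labels, x@barcodes))

#' @rdname SCPartition-accessors
#' @export
setMethod("nClusters", "SCPartition", function(x) x@nClusters)

#' @rdname SCPartition-accessors
#' @export
setMethod("trueLabels", "SCPartition", function(x)
  if (is.null(x@truth)) NULL else setNames(x@truth, x@barcodes))

## ---- show ------------------------------------------------------------------

setMethod("show", "HistoImage", function(object) {
  cat("HistoImage:", nrow(object@pixels), "x", ncol(object@pixels),
      "px, intensity scale 0-", format(object@maxval), "\n", sep = "")
  if (!is.null(object@foreground))
    cat("  foreground: ", sum(object@foreground), " px (",
        round(100 * mean(object@foreground), 1), "%)\n", sep = "")
})

setMethod("show", "SpotExperiment", function(object) {
  callNextMethod()
  cat("in-tissue spots:", sum(inTissue(object)), "/", ncol(object), "\n")
  if (!is.null(object@image))
    cat("image: ", nrow(object@image@pixels), "x", ncol(object@image@pixels),
        " px, spot diameter ", format(object@spotDiameter), " px\n", sep = "")
})

setMethod("show", "SimilarityNetwork", function(object) {
  cat("SimilarityNetwork (role ", object@role, "): ", object@nSpots,
      " spots, ", nrow(object@edges), " edges", sep = "")
  if (nrow(object@edges))
    cat(", weights in [", format(min(object@edges$w), digits = 4), ", ",
        format(max(object@edges$w), digits = 4), "]", sep = "")
  cat("\n")
})

setMethod("show", "SCPartition", function(object) {
  cat("SCPartition: ", length(object@labels), " spots in ", object@nClusters,
      " clusters (", object@method, ")\n", sep = "")
  print(table(cluster = object@labels))
  if (!is.null(object@truth)) cat("ground truth attached\n")
})

setMethod("show", "NoiseConfig", function(object) {
  cat("NoiseConfig: phi=", object@phi, ", sigma=(", object@sigma1, ",",
      object@sigma2, "), rho=", object@rho, ", dropoutRate=",
      object@dropoutRate, ", seed=", object@seed, "\n", sep = "")
})
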