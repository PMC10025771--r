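#' @rdname SpotExperiment-accessors
#' @export
setGeneric("arrayCoords", function(x) standardGeneric("arrayCoords"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("inTissue", function(x) standardGeneric("inTissue"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("histoImage", function(x) standardGeneric("histoImage"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("histoImage<-", function(x, value) standardGeneric("histoImage<-"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("spotDiameter", function(x) standardGeneric("spotDiameter"))

#' @rdname SimilarityNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SimilarityNetwork-accessors
#' @export
setGeneric("networkRole", function(x) standardGeneric("networkRole"))

#' @rdname SCPartition-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname SCPartition-accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname SCPartition-accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
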