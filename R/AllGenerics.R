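#' Accessors for package classes
#'
#' @param x a \linkS4class{CopyNumberTrack}, \linkS4class{SVCallSet} or
#'   \linkS4class{FeatureDB}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cnRatioValues", function(x) standardGeneric("cnRatioValues"))

#' @rdname accessors
#' @export
setGeneric("sampleNorm", function(x) standardGeneric("sampleNorm"))

#' @rdname accessors
#' @export
setGeneric("controlNorm", function(x) standardGeneric("controlNorm"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("maskedBins", function(x) standardGeneric("maskedBins"))

#' @rdname accessors
#' @export
setGeneric("contigName", function(x) standardGeneric("contigName"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname accessors
#' @export
setGeneric("regulatoryRanges", function(x) standardGeneric("regulatoryRanges"))
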