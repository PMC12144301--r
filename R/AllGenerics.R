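#' @rdname QuantExperiment-class
#' @param x a QuantExperiment.
#' @export
setGeneric("quantValues", function(x) standardGeneric("quantValues"))

#' @rdname QuantExperiment-class
#' @export
setGeneric("quantScale", function(x) standardGeneric("quantScale"))

#' @rdname QuantExperiment-class
#' @export
setGeneric("referenceCondition", function(x) standardGeneric("referenceCondition"))

#' @rdname QuantExperiment-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname CorrectionFactorTable-class
#' @param x a CorrectionFactorTable.
#' @export
setGeneric("correctionFactors", function(x) standardGeneric("correctionFactors"))

#' @rdname CorrectionFactorTable-class
#' @export
setGeneric("uncorrectable", function(x) standardGeneric("uncorrectable"))

#' @rdname AlignmentHit-class
#' @param x an AlignmentHit.
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname AlignmentHit-class
#' @export
setGeneric("alignmentColumns", function(x) standardGeneric("alignmentColumns"))
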