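#' @rdname peakAreas
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname runMetadataAccessors
#' @export
setGeneric("runType", function(x) standardGeneric("runType"))

#' @rdname runMetadataAccessors
#' @export
setGeneric("injectionIndex", function(x) standardGeneric("injectionIndex"))

#' @rdname runMetadataAccessors
#' @export
setGeneric("runBatch", function(x) standardGeneric("runBatch"))

#' @rdname runMetadataAccessors
#' @export
setGeneric("dnaConcentration", function(x) standardGeneric("dnaConcentration"))

#' @rdname featureAnnotations
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))

#' @rdname featureAnnotations
#' @export
setGeneric("featureRt", function(x) standardGeneric("featureRt"))

#' @rdname subsetRuns
#' @export
setGeneric("subsetRuns", function(x, runTypes) standardGeneric("subsetRuns"))

#' @rdname normalizationAccessors
#' @export
setGeneric("correctedTable", function(object) standardGeneric("correctedTable"))

#' @rdname normalizationAccessors
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))

#' @rdname normalizationAccessors
#' @export
setGeneric("normMethod", function(object) standardGeneric("normMethod"))

#' @rdname normalizationAccessors
#' @export
setGeneric("rescaleConstant", function(object) standardGeneric("rescaleConstant"))

#' @rdname batchAlignMean
#' @export
setGeneric("batchAlignMean", function(object, ...)
    standardGeneric("batchAlignMean"))

#' @rdname countRetained
#' @export
setGeneric("countRetained", function(metrics) standardGeneric("countRetained"))
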