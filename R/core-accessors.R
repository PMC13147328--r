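#' Peak-area matrix of an AdductExperiment
#'
#' @param x an [AdductExperiment-class]
#' @return numeric matrix, features x runs, `NA` = missing cell.
#' @export
setMethod("peakAreas", "AdductExperiment", function(x)
    assay(x, "peakArea"))

#' Run metadata accessors
#'
#' `runType()` returns the per-run type (`"sample"`, `"iqc"`, `"eqc"` or
#' `"tech_replicate"`), `injectionIndex()` the 1-based injection order,
#' `runBatch()` the batch label and `dnaConcentration()` the per-run DNA
#' concentration in ng/uL (`NA` for QC runs).
#'
#' @param x an [AdductExperiment-class]
#' @return a vector along the runs (columns) of `x`.
#' @name runMetadataAccessors
NULL

#' @rdname runMetadataAccessors
#' @export
setMethod("runType", "AdductExperiment", function(x) colData(x)$runType)

#' @rdname runMetadataAccessors
#' @export
setMethod("injectionIndex", "AdductExperiment", function(x)
    colData(x)$injectionIndex)

#' @rdname runMetadataAccessors
#' @export
setMethod("runBatch", "AdductExperiment", function(x) colData(x)$batch)

#' @rdname runMetadataAccessors
#' @export
setMethod("dnaConcentration", "AdductExperiment", function(x)
    colData(x)$dnaConcentration)

#' Feature annotation accessors
#'
#' `featureMz()` and `featureRt()` return the per-feature m/z (Da) and
#' retention time (seconds) annotations.  Feature identity is the row name;
#' m/z and RT are annotations, never keys.
#'
#' @param x an [AdductExperiment-class]
#' @return numeric vector along the features (rows) of `x`.
#' @name featureAnnotations
NULL

#' @rdname featureAnnotations
#' @export
setMethod("featureMz", "AdductExperiment", function(x) rowData(x)$mz)

#' @rdname featureAnnotations
#' @export
setMethod("featureRt", "AdductExperiment", function(x) rowData(x)$rt)

#' Restrict a table to runs of given types
#'
#' Keeps only columns whose run type is in `runTypes`; column order (and
#' hence injection order) and all cell values are preserved exactly.
#'
#' @param x an [AdductExperiment-class]
#' @param runTypes non-empty character subset of
#'   `c("sample", "iqc", "eqc", "tech_replicate")`
#' @return an [AdductExperiment-class] with the matching runs.
#' @examples
#' sim <- simulateAdductTable(adductSimConfig(nSamples = 10, nFeatures = 5))
#' subsetRuns(sim$experiment, "sample")
#' @export
setMethod("subsetRuns", "AdductExperiment", function(x, runTypes) {
    if (length(runTypes) == 0)
        stop("runTypes must be non-empty")
    bad <- setdiff(runTypes, .RUN_TYPES)
    if (length(bad))
        stop("unknown run type(s): ", paste(bad, collapse = ", "))
    keep <- runType(x) %in% runTypes
    if (!any(keep))
        stop("no runs of type(s): ", paste(runTypes, collapse = ", "))
    x[, keep]
})

#' Accessors for NormalizationResult
#'
#' `correctedTable()` returns the corrected [AdductExperiment-class],
#' `normFactors()` the factor vector (sample-based methods) or
#' feature-by-run factor matrix (feature-based methods), `normMethod()` the
#' method label, and `rescaleConstant()` the median-factor constant(s) that
#' reverted the corrected data to the original intensity scale.
#'
#' @param object a [NormalizationResult-class]
#' @name normalizationAccessors
NULL

#' @rdname normalizationAccessors
#' @export
setMethod("correctedTable", "NormalizationResult", function(object)
    object@corrected)

#' @rdname normalizationAccessors
#' @export
setMethod("normFactors", "NormalizationResult", function(object)
    object@factors)

#' @rdname normalizationAccessors
#' @export
setMethod("normMethod", "NormalizationResult", function(object)
    object@method)

#' @rdname normalizationAccessors
#' @export
setMethod("rescaleConstant", "NormalizationResult", function(object)
    object@rescale)
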