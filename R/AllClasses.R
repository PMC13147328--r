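#' @import methods
#' @importFrom stats median mad coef pt pnorm loess loess.control predict
#'   runif rnorm setNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   colData colData<- rowData rowData<-
NULL

## run types recognised throughout the package
.RUN_TYPES <- c("sample", "iqc", "eqc", "tech_replicate")

## run types that constitute pooled QC material
.QC_TYPES <- c("iqc", "eqc", "tech_replicate")

#' AdductExperiment: a feature-by-run peak-area table with run metadata
#'
#' `AdductExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with the invariants an untargeted DNA adductomics feature table must
#' satisfy after peak picking.  The single assay `"peakArea"` holds
#' non-negative peak areas (arbitrary intensity units) with `NA` for missing
#' cells; zero is a valid measured intensity and is never treated as missing.
#' Columns are runs ordered by injection index; `colData` carries
#' `injectionIndex` (1-based, unique, strictly increasing with column
#' order), `runType` (one of `"sample"`, `"iqc"`, `"eqc"`,
#' `"tech_replicate"`), `batch` and, for sample runs, `dnaConcentration`
#' (ng/uL).  `rowData` carries the feature annotations `mz` (Da) and `rt`
#' (seconds); the feature identity is the row name, m/z and RT are
#' annotations only.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @aliases AdductExperiment-class
#' @seealso [readAdductTable()], [simulateAdductTable()], [subsetRuns()]
#' @export
setClass("AdductExperiment", contains = "SummarizedExperiment")

.validAdductExperiment <- function(object) {
    msg <- NULL
    if (!"peakArea" %in% SummarizedExperiment::assayNames(object))
        return("assay 'peakArea' is required")
    v <- assay(object, "peakArea")
    cd <- colData(object)
    rd <- rowData(object)
    fid <- rownames(object)
    rid <- colnames(object)
    if (is.null(fid) || anyNA(fid) || any(fid == ""))
        msg <- c(msg, "feature ids (rownames) must be non-empty")
    else if (anyDuplicated(fid))
        msg <- c(msg, "feature ids must be unique")
    if (is.null(rid) || anyNA(rid) || any(rid == ""))
        msg <- c(msg, "run ids (colnames) must be non-empty")
    else if (anyDuplicated(rid))
        msg <- c(msg, "run ids must be unique")
    if (any(v[!is.na(v)] < 0))
        msg <- c(msg, "peak areas must be non-negative (NA encodes missing)")
    for (col in c("injectionIndex", "runType", "batch"))
        if (!col %in% names(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("injectionIndex" %in% names(cd)) {
        ii <- cd$injectionIndex
        if (anyNA(ii) || any(ii < 1) || any(ii != as.integer(ii)))
            msg <- c(msg, "injectionIndex must be positive integers")
        else if (anyDuplicated(ii))
            msg <- c(msg, "injectionIndex must be unique per run")
        else if (is.unsorted(ii, strictly = TRUE))
            msg <- c(msg, "columns must be ordered by increasing injectionIndex")
    }
    if ("runType" %in% names(cd) && !all(cd$runType %in% .RUN_TYPES))
        msg <- c(msg, sprintf("runType must be one of: %s",
                              paste(.RUN_TYPES, collapse = ", ")))
    if ("dnaConcentration" %in% names(cd)) {
        conc <- cd$dnaConcentration
        if (any(!is.na(conc) & conc <= 0))
            msg <- c(msg, "dnaConcentration must be missing or > 0")
    }
    if (all(c("mz", "rt") %in% names(rd))) {
        if (any(is.na(rd$mz)) || any(rd$mz <= 0))
            msg <- c(msg, "feature mz must be > 0")
        if (any(is.na(rd$rt)) || any(rd$rt < 0))
            msg <- c(msg, "feature rt must be >= 0")
    } else msg <- c(msg, "rowData columns 'mz' and 'rt' are required")
    if (is.null(msg)) TRUE else msg
}

setValidity("AdductExperiment", .validAdductExperiment)

#' Construct an AdductExperiment
#'
#' @param peakArea numeric matrix, features x runs; `NA` encodes a missing
#'   cell, all present values must be non-negative.  Row names are feature
#'   ids, column names run ids (taken from `runData$run_id` when absent).
#' @param runData data.frame of per-run metadata with columns `run_id`,
#'   `injection_index`, `run_type`, `batch` and optionally
#'   `dna_concentration` (ng/uL, sample runs only).
#' @param featureData data.frame of per-feature metadata with columns
#'   `feature_id`, `mz` (Da) and `rt` (seconds); may be `NULL` only when
#'   `peakArea` already carries `mz`/`rt` row annotations.
#'
#' Runs are re-ordered by `injection_index` when the supplied order differs
#' (a message is emitted); run order in the object is always injection
#' order.
#'
#' @return A validated [AdductExperiment-class] object.
#' @examples
#' pa <- matrix(c(10, 20, 30, 40, 50, 60), nrow = 2,
#'              dimnames = list(c("FT1", "FT2"), c("R1", "R2", "R3")))
#' runs <- data.frame(run_id = c("R1", "R2", "R3"), injection_index = 1:3,
#'                    run_type = c("eqc", "sample", "sample"), batch = "B1",
#'                    dna_concentration = c(NA, 50, 60))
#' feats <- data.frame(feature_id = c("FT1", "FT2"),
#'                     mz = c(152.06, 303.12), rt = c(100, 420))
#' ae <- AdductExperiment(pa, runs, feats)
#' @export
AdductExperiment <- function(peakArea, runData, featureData = NULL) {
    peakArea <- as.matrix(peakArea)
    storage.mode(peakArea) <- "double"
    runData <- as.data.frame(runData)
    req <- c("run_id", "injection_index", "run_type", "batch")
    if (!all(req %in% names(runData)))
        stop("runData must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(runData$run_id))
        stop("duplicate run_id in run metadata")
    if (anyDuplicated(runData$injection_index))
        stop("duplicate injection_index in run metadata")
    if (is.null(colnames(peakArea)))
        colnames(peakArea) <- runData$run_id
    missingRuns <- setdiff(colnames(peakArea), runData$run_id)
    if (length(missingRuns))
        stop("runs in values absent from run metadata: ",
             paste(missingRuns, collapse = ", "))
    runData <- runData[match(colnames(peakArea), runData$run_id), , drop = FALSE]
    ord <- order(runData$injection_index)
    if (is.unsorted(runData$injection_index, strictly = TRUE)) {
        message("re-ordering runs by injection_index")
        runData <- runData[ord, , drop = FALSE]
        peakArea <- peakArea[, ord, drop = FALSE]
    }
    if (!is.null(featureData)) {
        featureData <- as.data.frame(featureData)
        if (!all(c("feature_id", "mz", "rt") %in% names(featureData)))
            stop("featureData must have columns feature_id, mz, rt")
        if (anyDuplicated(featureData$feature_id))
            stop("duplicate feature_id in feature metadata")
        if (is.null(rownames(peakArea)))
            rownames(peakArea) <- featureData$feature_id
        missingFeat <- setdiff(rownames(peakArea), featureData$feature_id)
        if (length(missingFeat))
            stop("features in values absent from feature metadata: ",
                 paste(utils::head(missingFeat, 5), collapse = ", "))
        featureData <- featureData[match(rownames(peakArea),
                                         featureData$feature_id), , drop = FALSE]
        rd <- DataFrame(mz = as.numeric(featureData$mz),
                        rt = as.numeric(featureData$rt),
                        row.names = rownames(peakArea))
    } else {
        rd <- DataFrame(row.names = rownames(peakArea))
    }
    conc <- if ("dna_concentration" %in% names(runData))
        as.numeric(runData$dna_concentration) else rep(NA_real_, nrow(runData))
    cd <- DataFrame(injectionIndex = as.integer(runData$injection_index),
                    runType = as.character(runData$run_type),
                    batch = as.character(runData$batch),
                    dnaConcentration = conc,
                    row.names = runData$run_id)
    se <- SummarizedExperiment(assays = list(peakArea = peakArea),
                               colData = cd, rowData = rd)
    new("AdductExperiment", se)
}

#' @describeIn AdductExperiment compact display
#' @param object an `AdductExperiment`
#' @export
setMethod("show", "AdductExperiment", function(object) {
    tab <- table(factor(runType(object), levels = .RUN_TYPES))
    v <- peakAreas(object)
    cat(sprintf("AdductExperiment: %d features x %d runs\n",
                nrow(object), ncol(object)))
    cat(sprintf("  runs: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    cat(sprintf("  batches: %s\n",
                paste(unique(runBatch(object)), collapse = ", ")))
    cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(v)),
                100 * mean(is.na(v))))
    invisible(NULL)
})

## ---------------------------------------------------------------------------

setClassUnion("numeric_OR_matrix", c("numeric", "matrix"))

#' NormalizationResult: a corrected table plus the factor surface applied
#'
#' Produced by [normalizeDrift()], [lmbscCorrect()], [qcRlscCorrect()] and
#' [batchAlignMean()].  Every non-missing corrected cell satisfies
#' `corrected * factor / rescale == raw` (within floating tolerance): the
#' raw value was divided by a strictly positive normalization factor and
#' multiplied back by the median factor so corrected data remain on the
#' original intensity scale.  Sample-based methods (`tic`, `median`) store a
#' per-run factor vector and a scalar rescale constant; feature-based
#' methods (`fbsc_b`, `lomec`, `lmbsc`, `qc_rlsc`) store a feature-by-run
#' factor matrix and a per-feature rescale vector.
#'
#' @slot corrected the corrected [AdductExperiment-class]
#' @slot factors per-run numeric vector or feature-by-run matrix of strictly
#'   positive normalization factors (unitless)
#' @slot method one of `"none"`, `"tic"`, `"median"`, `"fbsc_b"`, `"lomec"`,
#'   `"lmbsc"`, `"qc_rlsc"`
#' @slot rescale the median-factor constant(s) used to revert the scale
#' @export
setClass("NormalizationResult",
         representation(corrected = "AdductExperiment",
                        factors = "numeric_OR_matrix",
                        method = "character",
                        rescale = "numeric"))

setValidity("NormalizationResult", function(object) {
    msg <- NULL
    x <- object@corrected
    f <- object@factors
    if (is.matrix(f)) {
        if (!all(dim(f) == dim(x)))
            msg <- c(msg, "factor matrix dimensions must match the table")
        if (length(object@rescale) != nrow(x))
            msg <- c(msg, "feature-based rescale must be per-feature")
    } else {
        if (length(f) != ncol(x))
            msg <- c(msg, "factor vector length must equal the number of runs")
        if (length(object@rescale) != 1L)
            msg <- c(msg, "sample-based rescale must be a scalar")
    }
    if (any(f <= 0))
        msg <- c(msg, "normalization factors must be strictly positive")
    if (length(object@method) != 1L ||
        !object@method %in% c("none", "tic", "median", "fbsc_b", "lomec",
                              "lmbsc", "qc_rlsc"))
        msg <- c(msg, "unknown method label")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn NormalizationResult compact display
#' @param object a `NormalizationResult`
#' @export
setMethod("show", "NormalizationResult", function(object) {
    kind <- if (is.matrix(object@factors)) "feature-based" else "sample-based"
    cat(sprintf("NormalizationResult: method '%s' (%s factors)\n",
                object@method, kind))
    show(object@corrected)
    invisible(NULL)
})

## ---------------------------------------------------------------------------

#' QcMetrics: per-feature robust quality metrics and retention flags
#'
#' Per-feature RSD* (robust relative standard deviation over technical
#' replicate runs) and D-ratio (MAD of replicates over MAD of samples),
#' with strict-inequality pass flags at the chosen thresholds and
#' `retained = rsdPass & dratioPass`.  Degenerate features (zero replicate
#' median or zero sample MAD) carry `NA` metrics and fail.
#'
#' @slot featureId character feature ids
#' @slot rsdStar per-feature RSD* (unitless fraction, `NA` when degenerate)
#' @slot dRatio per-feature D-ratio (unitless, `NA` when degenerate)
#' @slot rsdPass,dratioPass,retained logical flags
#' @slot thresholds named numeric `c(rsd = ..., dratio = ...)`
#' @seealso [evaluateFeatures()], [countRetained()]
#' @export
setClass("QcMetrics",
         representation(featureId = "character", rsdStar = "numeric",
                        dRatio = "numeric", rsdPass = "logical",
                        dratioPass = "logical", retained = "logical",
                        thresholds = "numeric"))

setValidity("QcMetrics", function(object) {
    n <- length(object@featureId)
    lens <- c(length(object@rsdStar), length(object@dRatio),
              length(object@rsdPass), length(object@dratioPass),
              length(object@retained))
    msg <- NULL
    if (any(lens != n)) msg <- c(msg, "all per-feature slots must align")
    if (any(object@rsdStar < 0, na.rm = TRUE) ||
        any(object@dRatio < 0, na.rm = TRUE))
        msg <- c(msg, "metrics must be non-negative")
    if (!identical(object@retained, object@rsdPass & object@dratioPass))
        msg <- c(msg, "retained must equal rsdPass & dratioPass")
    if (!all(c("rsd", "dratio") %in% names(object@thresholds)))
        msg <- c(msg, "thresholds must be named 'rsd' and 'dratio'")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn QcMetrics compact display
#' @param object a `QcMetrics`
#' @export
setMethod("show", "QcMetrics", function(object) {
    cnt <- countRetained(object)
    cat(sprintf(
        "QcMetrics: %d features, thresholds RSD* < %g, D-ratio < %g\n",
        length(object@featureId), object@thresholds["rsd"],
        object@thresholds["dratio"]))
    cat(sprintf("  RSD* pass: %d, D-ratio pass: %d, retained: %d\n",
                cnt["nRsdPass"], cnt["nDratioPass"], cnt["nRetained"]))
    invisible(NULL)
})

#' @describeIn QcMetrics coerce to data.frame (one row per feature)
#' @param x a `QcMetrics`
#' @param ... ignored
#' @export
as.data.frame.QcMetrics <- function(x, ...) {
    data.frame(feature_id = x@featureId, rsd_star = x@rsdStar,
               d_ratio = x@dRatio, rsd_pass = x@rsdPass,
               dratio_pass = x@dratioPass, retained = x@retained,
               stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------

#' AdductSimConfig: study-design and noise parameters for the simulator
#'
#' Encodes the injection design and noise structure of a pooled-QC
#' untargeted LC-MS study: a lead-in of `nEqc` external QCs, blocks of
#' `blockSize` samples each followed by an internal QC pair whose second
#' vial is a technical replicate, a lead-out of `nEqc` external QCs;
#' feature-dependent multiplicative drift (sinusoid plus linear trend),
#' per-batch column effects, pooled-QC dilution, internal standards with
#' constant true level, per-sample DNA amounts, and intensity-dependent
#' (censoring) missingness.  See [simulateAdductTable()] for the exact
#' generative model and the methods vignette for the rationale behind the
#' defaults.
#'
#' @slot nSamples,nFeatures,nIstd,blockSize,nEqc,nBatches integers
#' @slot biologicalCv log-scale SD of sample abundances
#' @slot highBioFraction fraction of features given inflated biological
#'   variance; `highBioMultiplier` multiplies their variance
#' @slot highBioMultiplier see `highBioFraction`
#' @slot techCv multiplicative (log-scale) technical noise SD
#' @slot driftAmplitudeRange,driftPeriodRange,driftSlopeRange per-feature
#'   drift parameter ranges (amplitude unitless, period in injections,
#'   slope as total fractional change across the sequence)
#' @slot batchEffectSd log-scale SD of per-feature per-batch offsets
#' @slot qcDilution pooled-QC abundance relative to the mean sample, (0, 1]
#' @slot lod intensity below which censoring becomes likely
#' @slot missingSteepness logistic steepness of the censoring probability
#' @slot dnaConcMean,dnaConcCv per-sample DNA concentration (ng/uL)
#'   lognormal mean and CV
#' @slot intensityRange range of per-feature baseline intensities
#'   (log-uniform)
#' @slot seed integer RNG seed
#' @export
setClass("AdductSimConfig",
         representation(nSamples = "integer", nFeatures = "integer",
                        nIstd = "integer", blockSize = "integer",
                        nEqc = "integer", nBatches = "integer",
                        biologicalCv = "numeric", highBioFraction = "numeric",
                        highBioMultiplier = "numeric", techCv = "numeric",
                        driftAmplitudeRange = "numeric",
                        driftPeriodRange = "numeric",
                        driftSlopeRange = "numeric",
                        batchEffectSd = "numeric", qcDilution = "numeric",
                        lod = "numeric", missingSteepness = "numeric",
                        dnaConcMean = "numeric", dnaConcCv = "numeric",
                        intensityRange = "numeric", seed = "integer"))

setValidity("AdductSimConfig", function(object) {
    msg <- NULL
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be >= 1")
    if (object@nIstd < 0L) msg <- c(msg, "nIstd must be >= 0")
    if (object@nIstd > object@nFeatures)
        msg <- c(msg, "nIstd cannot exceed nFeatures")
    if (object@blockSize < 1L) msg <- c(msg, "blockSize must be >= 1")
    if (object@nEqc < 0L) msg <- c(msg, "nEqc must be >= 0")
    if (object@nBatches < 1L) msg <- c(msg, "nBatches must be >= 1")
    if (object@biologicalCv < 0) msg <- c(msg, "biologicalCv must be >= 0")
    if (object@techCv < 0) msg <- c(msg, "techCv must be >= 0")
    if (object@highBioFraction < 0 || object@highBioFraction > 1)
        msg <- c(msg, "highBioFraction must be in [0, 1]")
    for (nm in c("driftAmplitudeRange", "driftPeriodRange",
                 "driftSlopeRange", "intensityRange")) {
        r <- slot(object, nm)
        if (length(r) != 2L || r[1] > r[2])
            msg <- c(msg, sprintf("%s must be c(lo, hi) with lo <= hi", nm))
    }
    if (object@driftPeriodRange[1] <= 0)
        msg <- c(msg, "drift periods must be positive")
    if (object@qcDilution <= 0 || object@qcDilution > 1)
        msg <- c(msg, "qcDilution must be in (0, 1]")
    if (object@lod < 0) msg <- c(msg, "lod must be >= 0")
    if (object@missingSteepness <= 0)
        msg <- c(msg, "missingSteepness must be > 0")
    if (object@dnaConcMean <= 0 || object@dnaConcCv < 0)
        msg <- c(msg, "DNA concentration parameters must be positive")
    if (object@intensityRange[1] <= 0)
        msg <- c(msg, "intensityRange must be positive")
    if (object@batchEffectSd < 0) msg <- c(msg, "batchEffectSd must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn AdductSimConfig compact display
#' @param object an `AdductSimConfig`
#' @export
setMethod("show", "AdductSimConfig", function(object) {
    cat(sprintf(
        "AdductSimConfig: %d samples, %d features (%d ISTD), %d batch(es)\n",
        object@nSamples, object@nFeatures, object@nIstd, object@nBatches))
    cat(sprintf("  blocks of %d samples + iQC pair, %d lead-in/out eQCs\n",
                object@blockSize, object@nEqc))
    cat(sprintf(
        "  bioCV %.2f, techCV %.2f, drift amp [%.2f, %.2f], seed %d\n",
        object@biologicalCv, object@techCv, object@driftAmplitudeRange[1],
        object@driftAmplitudeRange[2], object@seed))
    invisible(NULL)
})

#' SimTruth: the simulator's ground truth
#'
#' Holds the latent quantities behind a simulated table so corrections can
#' be validated against what a perfect method could recover: the
#' drift/batch/noise-free abundance matrix, the multiplicative drift
#' surface, the per-feature per-batch factors, and the internal-standard
#' feature ids (whose true abundance is constant across runs by
#' construction).
#'
#' @slot trueAbundance features x runs matrix before drift/batch/noise
#' @slot driftSurface features x runs strictly positive drift factors
#' @slot batchFactors features x batches multiplicative offsets
#' @slot istdIds character ids of internal-standard features
#' @seealso [simulateAdductTable()], [truthDriftRsd()]
#' @export
setClass("SimTruth",
         representation(trueAbundance = "matrix", driftSurface = "matrix",
                        batchFactors = "matrix", istdIds = "character"))

setValidity("SimTruth", function(object) {
    msg <- NULL
    if (!all(dim(object@trueAbundance) == dim(object@driftSurface)))
        msg <- c(msg, "trueAbundance and driftSurface must align")
    if (any(object@driftSurface <= 0))
        msg <- c(msg, "driftSurface must be strictly positive")
    ist <- object@istdIds
    if (length(ist)) {
        rows <- object@trueAbundance[ist, , drop = FALSE]
        if (any(apply(rows, 1, function(r) diff(range(r)) > 1e-8 * max(r))))
            msg <- c(msg, "ISTD rows of trueAbundance must be constant")
    }
    if (is.null(msg)) TRUE else msg
})
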