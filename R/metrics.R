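#' Robust relative standard deviation (RSD*)
#'
#' The scaled median absolute deviation divided by the absolute median:
#' `1.4826 * median(|x - median(x)|) / |median(x)|`.  The 1.4826
#' normal-consistency constant makes RSD* comparable to an ordinary CV for
#' Gaussian data, so the usual 0.2/0.3 retention thresholds apply.  RSD*
#' is invariant under multiplication by a positive constant.
#'
#' @param values at least two finite numeric values with non-zero median
#' @return non-negative unitless fraction.
#' @examples
#' rsdStar(c(1, 2, 3))   # 1.4826 * 1 / 2
#' @export
rsdStar <- function(values) {
    if (length(values) < 2) stop("need at least 2 values")
    if (any(!is.finite(values))) stop("values must be finite")
    m <- median(values)
    if (m == 0) stop("median is zero; RSD* undefined")
    mad(values, constant = 1.4826) / abs(m)
}

#' Dispersion ratio (D-ratio) of replicate to sample variation
#'
#' The ratio of the median absolute deviation in technical replicates to
#' the median absolute deviation in samples, `MAD(rep) / MAD(sample)`.
#' The MAD scaling constant cancels.  Low values flag features whose
#' technical variance is small relative to their variation across samples.
#'
#' @param repValues intensities in technical replicate runs (>= 2)
#' @param sampleValues intensities in sample runs (>= 2, non-zero MAD)
#' @return non-negative unitless ratio.
#' @examples
#' dRatio(c(9, 10, 11), c(5, 10, 15))   # 0.2
#' @export
dRatio <- function(repValues, sampleValues) {
    if (length(repValues) < 2 || length(sampleValues) < 2)
        stop("need at least 2 values in each group")
    if (any(!is.finite(repValues)) || any(!is.finite(sampleValues)))
        stop("values must be finite")
    ms <- mad(sampleValues, constant = 1)
    if (ms == 0)
        stop("zero sample MAD; feature is degenerate for the D-ratio")
    mad(repValues, constant = 1) / ms
}

#' Per-feature RSD* over a run group
#'
#' Applies [rsdStar()] feature-wise over the runs of the requested types;
#' used both for replicate-based feature evaluation and for ISTD
#' evaluation over sample runs.  Features with zero median in the group
#' give `NA` (with a warning tally) rather than an error.
#'
#' @param x a complete [AdductExperiment-class]
#' @param runTypes run group over which to compute the RSD*
#' @return named numeric vector, one RSD* (or `NA`) per feature.
#' @export
featureRsd <- function(x, runTypes = "sample") {
    stopifnot(is(x, "AdductExperiment"))
    sub <- subsetRuns(x, runTypes)
    v <- peakAreas(sub)
    if (anyNA(v)) stop("table must be complete (impute first)")
    if (ncol(v) < 2) stop("need at least 2 runs of the requested type(s)")
    out <- apply(v, 1, function(r) {
        m <- median(r)
        if (m == 0) NA_real_ else mad(r, constant = 1.4826) / abs(m)
    })
    nbad <- sum(is.na(out))
    if (nbad > 0)
        warning(nbad, " feature(s) with zero median in the run group")
    out
}

#' Evaluate features by RSD* and D-ratio thresholds
#'
#' Computes, per feature, the RSD* over technical-replicate runs and the
#' D-ratio of technical-replicate to sample variation, and flags features
#' passing *strict* thresholds (`rsd_star < rsdThreshold` and
#' `d_ratio < dratioThreshold`); a feature is retained iff both pass.
#' Degenerate features (zero replicate median or zero sample MAD) get `NA`
#' metrics and fail.
#'
#' @param x a complete [AdductExperiment-class] with at least two
#'   technical-replicate and two sample runs
#' @param rsdThreshold RSD* threshold (e.g. 0.2 or 0.3)
#' @param dratioThreshold D-ratio threshold (e.g. 0.4 or 0.5)
#' @param replicateType run type(s) forming the replicate group; default
#'   the technical replicates (the second vial of each internal QC pair)
#' @return a [QcMetrics-class]
#' @examples
#' sim <- simulateAdductTable(adductSimConfig(nSamples = 20, nFeatures = 30))
#' evaluateFeatures(imputeHalfMin(sim$experiment), 0.3, 0.5)
#' @export
evaluateFeatures <- function(x, rsdThreshold = 0.3, dratioThreshold = 0.5,
                             replicateType = "tech_replicate") {
    stopifnot(is(x, "AdductExperiment"))
    v <- peakAreas(x)
    if (anyNA(v)) stop("table must be complete (impute first)")
    rep_ <- runType(x) %in% replicateType
    samp <- runType(x) == "sample"
    if (sum(rep_) < 2) stop("need at least 2 replicate runs")
    if (sum(samp) < 2) stop("need at least 2 sample runs")
    vr <- v[, rep_, drop = FALSE]
    vs <- v[, samp, drop = FALSE]
    rsd <- apply(vr, 1, function(r) {
        m <- median(r)
        if (m == 0) NA_real_ else mad(r, constant = 1.4826) / abs(m)
    })
    dr <- vapply(seq_len(nrow(v)), function(i) {
        ms <- mad(vs[i, ], constant = 1)
        if (ms == 0) NA_real_ else mad(vr[i, ], constant = 1) / ms
    }, numeric(1))
    rsdPass <- !is.na(rsd) & rsd < rsdThreshold
    drPass <- !is.na(dr) & dr < dratioThreshold
    new("QcMetrics", featureId = rownames(v), rsdStar = unname(rsd),
        dRatio = dr, rsdPass = unname(rsdPass), dratioPass = drPass,
        retained = unname(rsdPass) & drPass,
        thresholds = c(rsd = rsdThreshold, dratio = dratioThreshold))
}

#' Count features passing the quality thresholds
#'
#' @param metrics a [QcMetrics-class]
#' @return named integer vector `c(nRsdPass, nDratioPass, nRetained)`.
#' @rdname countRetained
#' @export
setMethod("countRetained", "QcMetrics", function(metrics) {
    c(nRsdPass = sum(metrics@rsdPass),
      nDratioPass = sum(metrics@dratioPass),
      nRetained = sum(metrics@retained))
})

#' Ids of retained features
#'
#' @param metrics a [QcMetrics-class]
#' @return character vector of feature ids with `retained = TRUE`.
#' @export
retainedFeatures <- function(metrics) {
    stopifnot(is(metrics, "QcMetrics"))
    metrics@featureId[metrics@retained]
}
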