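## Advisory estimation of upstream peak-picking parameters from EIC-level
## summaries.  EICs are plain data.frames with columns run_id, target_id,
## rt (s), mz (Da), intensity; one trace = one (target_id, run_id) pair.

.splitTraces <- function(eics) {
    req <- c("run_id", "rt", "mz", "intensity")
    if (!all(req %in% names(eics)))
        stop("EIC data must have columns: ", paste(req, collapse = ", "))
    key <- if ("target_id" %in% names(eics))
        paste(eics$target_id, eics$run_id) else eics$run_id
    lapply(split(eics, key), function(tr) tr[order(tr$rt), , drop = FALSE])
}

#' Estimate the mass-accuracy (ppm) spread of a target
#'
#' Collects the m/z values of apex-region points (intensity at or above
#' `apexFraction` of each trace's apex, approximating a restricted window
#' with a single mass peak per spectrum) across all traces of one target,
#' and returns the maximum pairwise absolute m/z difference divided by the
#' median m/z, expressed in ppm.  Invariant to intensity rescaling and RT
#' shifts.
#'
#' @param eics data.frame of EIC points for one target (columns `run_id`,
#'   `rt`, `mz`, `intensity`; optional `target_id`)
#' @param apexFraction intensity gate as a fraction of each trace's apex
#' @return the m/z spread in ppm.
#' @examples
#' eic <- data.frame(run_id = "r1", rt = c(1, 2), mz = c(500, 500.001),
#'                   intensity = c(90, 100))
#' estimatePpm(eic)   # 2 ppm
#' @export
estimatePpm <- function(eics, apexFraction = 0.5) {
    traces <- .splitTraces(eics)
    mzs <- unlist(lapply(traces, function(tr) {
        apex <- max(tr$intensity)
        tr$mz[tr$intensity >= apexFraction * apex & tr$intensity > 0]
    }), use.names = FALSE)
    if (length(mzs) < 2)
        stop("fewer than 2 points qualify above the intensity gate")
    (max(mzs) - min(mzs)) / median(mzs) * 1e6
}

.traceWidth <- function(tr, heightFraction) {
    int <- tr$intensity
    rt <- tr$rt
    n <- length(int)
    if (n < 3) stop("trace too short")
    baseline <- median(sort(int)[seq_len(max(1, floor(n / 4)))])
    apexI <- which.max(int)
    apex <- int[apexI]
    if (apex <= baseline) stop("flat trace: no peak above baseline")
    thr <- baseline + heightFraction * (apex - baseline)
    lo <- apexI
    while (lo > 1 && int[lo - 1] >= thr) lo <- lo - 1
    hi <- apexI
    while (hi < n && int[hi + 1] >= thr) hi <- hi + 1
    ## linear interpolation of the threshold crossings beyond the region
    left <- rt[lo]
    if (lo > 1)
        left <- rt[lo] - (rt[lo] - rt[lo - 1]) *
            (int[lo] - thr) / (int[lo] - int[lo - 1])
    right <- rt[hi]
    if (hi < n)
        right <- rt[hi] + (rt[hi + 1] - rt[hi]) *
            (int[hi] - thr) / (int[hi] - int[hi + 1])
    scan <- median(diff(rt))
    max(right - left, scan)
}

#' Estimate chromatographic peak-width bounds
#'
#' Per trace, the peak width is the RT extent of the region around the
#' apex where intensity stays at or above `heightFraction` of the
#' baseline-subtracted apex (baseline = median of the trace's lowest
#' intensity quartile), with the threshold crossings linearly
#' interpolated; widths are floored at one scan interval.  Returns the
#' minimum and maximum width over traces, the values to use as peak-width
#' bounds for centroid-based peak detection.
#'
#' @param eics data.frame of EIC points (columns `run_id`, `rt`, `mz`,
#'   `intensity`; optional `target_id`)
#' @param heightFraction width measurement height, fraction of the
#'   baseline-subtracted apex (default 0.05)
#' @return named numeric `c(min = ..., max = ...)` in seconds.
#' @export
estimatePeakwidth <- function(eics, heightFraction = 0.05) {
    traces <- .splitTraces(eics)
    w <- vapply(traces, .traceWidth, numeric(1),
                heightFraction = heightFraction)
    c(min = min(w), max = max(w))
}

#' Suggest a minimum detection fraction for feature grouping
#'
#' Given per-target detection rates (fraction of sample runs in which the
#' target's peak was detected), returns `safety * min(rates)` rounded
#' *down* to two decimals and floored at 0.01 -- a grouping threshold low
#' enough that the rarest known target still forms a feature, with a
#' safety margin for pooled-QC dilution.
#'
#' @param detectionRates per-target detection rates in (0, 1]
#' @param safety multiplicative safety margin (default 0.75)
#' @return suggested minimum fraction.
#' @examples
#' suggestMinFraction(c(0.078, 0.5, 0.9))   # 0.05
#' @export
suggestMinFraction <- function(detectionRates, safety = 0.75) {
    if (length(detectionRates) == 0) stop("no detection rates supplied")
    if (any(detectionRates <= 0) || any(detectionRates > 1))
        stop("detection rates must lie in (0, 1]")
    max(0.01, floor(safety * min(detectionRates) * 100) / 100)
}

#' Advise peak-picking parameters from target EICs
#'
#' Bundles [estimatePpm()] (per target, reporting the maximum spread
#' across targets alongside a configurable instrument floor),
#' [estimatePeakwidth()] and [suggestMinFraction()] into one advisory
#' record ready to paste into an untargeted peak-detection parameter
#' block.  The measured ppm spread and the floor are both reported; the
#' choice between them is left to the analyst.
#'
#' @param eics data.frame of EIC points with `target_id`
#' @param detectionRates optional per-target detection rates for
#'   [suggestMinFraction()]
#' @param ppmFloor instrument-advertised mass-accuracy floor to report
#'   alongside the measured spread (default 5 ppm)
#' @param safety safety margin for the minimum fraction
#' @return list with `ppm_measured`, `ppm_floor`, `ppm_suggested`,
#'   `peakwidth` and (when rates are given) `min_fraction`.
#' @export
advisePeakPicking <- function(eics, detectionRates = NULL, ppmFloor = 5,
                              safety = 0.75) {
    if (!"target_id" %in% names(eics))
        stop("EIC data must have a target_id column")
    ppmPerTarget <- vapply(split(eics, eics$target_id), estimatePpm,
                           numeric(1))
    measured <- max(ppmPerTarget)
    out <- list(ppm_measured = measured, ppm_floor = ppmFloor,
                ppm_suggested = max(measured, ppmFloor),
                peakwidth = estimatePeakwidth(eics))
    if (!is.null(detectionRates))
        out$min_fraction <- suggestMinFraction(detectionRates, safety)
    out
}
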