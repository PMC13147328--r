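## All six correction strategies share one contract: a strictly positive
## normalization factor per run (sample-based) or per feature and run
## (feature-based); corrected = raw / factor * median(factor), the median
## taken over runs (sample-based) or over the feature's own factors
## (feature-based), so corrected data sit on the original intensity scale.

.checkComplete <- function(x) {
    if (anyNA(peakAreas(x)))
        stop("table contains missing cells; filter and impute first")
}

.qcMask <- function(x, qcTypes) {
    bad <- setdiff(qcTypes, .RUN_TYPES)
    if (length(bad))
        stop("unknown QC run type(s): ", paste(bad, collapse = ", "))
    runType(x) %in% qcTypes
}

.applySampleFactors <- function(x, factors, method) {
    if (any(!is.finite(factors)) || any(factors <= 0)) {
        run <- colnames(x)[which(!is.finite(factors) | factors <= 0)[1]]
        stop("non-positive normalization factor for run ", run)
    }
    resc <- median(factors)
    v <- sweep(peakAreas(x), 2, factors, "/") * resc
    assay(x, "peakArea") <- v
    new("NormalizationResult", corrected = x,
        factors = setNames(factors, colnames(x)), method = method,
        rescale = resc)
}

.applyFeatureFactors <- function(x, factors, method) {
    bad <- which(!is.finite(factors) | factors <= 0)
    if (length(bad)) {
        i <- arrayInd(bad[1], dim(factors))
        stop(sprintf("non-positive normalization factor for feature %s, run %s",
                     rownames(x)[i[1]], colnames(x)[i[2]]))
    }
    resc <- apply(factors, 1, median)
    v <- peakAreas(x) / factors * resc
    assay(x, "peakArea") <- v
    dimnames(factors) <- dimnames(x)
    new("NormalizationResult", corrected = x, factors = factors,
        method = method, rescale = resc)
}

#' Normalize a feature table by one of six strategies
#'
#' Dispatches to the per-method factor computation and applies the common
#' divide-then-rescale step: every cell is divided by its normalization
#' factor and multiplied by the median factor (over runs for the
#' sample-based `tic` and `median` methods, over each feature's own
#' factors for the feature-based `fbsc_b`, `lomec`, `lmbsc` and `qc_rlsc`
#' methods).  `method = "none"` returns the input with unit factors.
#'
#' @param x a complete [AdductExperiment-class] (impute first)
#' @param method one of `"none"`, `"tic"`, `"median"`, `"fbsc_b"`,
#'   `"lomec"`, `"lmbsc"`, `"qc_rlsc"`
#' @param qcTypes run types supplying QC intensities for the QC-dependent
#'   methods; defaults to the internal QC pairs
#'   (`c("iqc", "tech_replicate")`), excluding the bracketing eQCs
#' @param windowK window size for `lomec`
#' @param alpha slope-significance level for `lmbsc`
#' @param degree,spanGrid LOESS settings for `qc_rlsc`
#' @return a [NormalizationResult-class]
#' @examples
#' sim <- simulateAdductTable(adductSimConfig(nSamples = 20, nFeatures = 30))
#' res <- normalizeDrift(imputeHalfMin(sim$experiment), "qc_rlsc")
#' res
#' @export
normalizeDrift <- function(x, method = c("none", "tic", "median", "fbsc_b",
                                         "lomec", "lmbsc", "qc_rlsc"),
                           qcTypes = c("iqc", "tech_replicate"),
                           windowK = 4L, alpha = 0.05, degree = 2L,
                           spanGrid = seq(0.2, 0.95, by = 0.05)) {
    stopifnot(is(x, "AdductExperiment"))
    method <- match.arg(method)
    if (method == "none") {
        return(new("NormalizationResult", corrected = x,
                   factors = setNames(rep(1, ncol(x)), colnames(x)),
                   method = "none", rescale = 1))
    }
    .checkComplete(x)
    switch(method,
           tic = .applySampleFactors(x, ticFactors(x), "tic"),
           median = .applySampleFactors(x, medianFactors(x), "median"),
           fbsc_b = .applyFeatureFactors(x, fbscBFactors(x, qcTypes),
                                         "fbsc_b"),
           lomec = .applyFeatureFactors(x,
                                        lomecFactors(x, windowK, qcTypes),
                                        "lomec"),
           lmbsc = lmbscCorrect(x, alpha = alpha, qcTypes = qcTypes),
           qc_rlsc = qcRlscCorrect(x, degree = degree, spanGrid = spanGrid,
                                   qcTypes = qcTypes))
}

#' Total-ion-count normalization factors
#'
#' One factor per run: the sum of all feature intensities in that run.
#'
#' @param x a complete [AdductExperiment-class]
#' @return named positive numeric vector, one entry per run.
#' @export
ticFactors <- function(x) {
    .checkComplete(x)
    f <- colSums(peakAreas(x))
    if (any(f <= 0))
        stop("run(s) with zero total intensity: ",
             paste(colnames(x)[f <= 0], collapse = ", "))
    f
}

#' Median normalization factors
#'
#' One factor per run: the median over features of that run's intensities.
#'
#' @param x a complete [AdductExperiment-class]
#' @return named positive numeric vector, one entry per run.
#' @export
medianFactors <- function(x) {
    .checkComplete(x)
    f <- apply(peakAreas(x), 2, median)
    if (any(f <= 0))
        stop("run(s) with zero median intensity: ",
             paste(colnames(x)[f <= 0], collapse = ", "))
    f
}

## group selected QC runs into "stations": maximal blocks of consecutive
## injection indices (an iQC pair injected back-to-back is one station)
.qcStations <- function(idx) {
    split(seq_along(idx), cumsum(c(1, diff(idx) > 1)))
}

#' Bracketing-QC (FBSC-B) normalization factors
#'
#' Feature-based signal correction from bracketing internal-QC injections:
#' for feature i and run j, the factor is the mean of feature i's
#' intensity over the nearest QC pair before and the nearest QC pair after
#' run j (four values when both sides exist, one pair at the sequence
#' edges; a QC run uses its own pair), divided by feature i's grand mean
#' over all selected QC runs.
#'
#' @param x a complete [AdductExperiment-class]
#' @param qcTypes run types forming the QC pairs; the default
#'   `c("iqc", "tech_replicate")` uses both vials of each internal QC pair
#'   and excludes eQCs; add `"eqc"` to use all QCs
#' @return features x runs matrix of positive factors.
#' @export
fbscBFactors <- function(x, qcTypes = c("iqc", "tech_replicate")) {
    .checkComplete(x)
    qc <- .qcMask(x, qcTypes)
    if (sum(qc) < 2) stop("need at least 2 QC runs for FBSC-B")
    vQc <- peakAreas(x)[, qc, drop = FALSE]
    qcIdx <- injectionIndex(x)[qc]
    stations <- .qcStations(qcIdx)
    stLo <- vapply(stations, function(s) min(qcIdx[s]), numeric(1))
    stHi <- vapply(stations, function(s) max(qcIdx[s]), numeric(1))
    allIdx <- injectionIndex(x)
    ## weight matrix: rows = runs, cols = selected QC runs
    W <- matrix(0, ncol(x), sum(qc))
    for (j in seq_len(ncol(x))) {
        ij <- allIdx[j]
        own <- which(stLo <= ij & stHi >= ij)
        members <- if (length(own)) {
            stations[[own[1]]]
        } else {
            prev <- which(stHi < ij)
            nxt <- which(stLo > ij)
            c(if (length(prev)) stations[[prev[which.max(stHi[prev])]]],
              if (length(nxt)) stations[[nxt[which.min(stLo[nxt])]]])
        }
        W[j, members] <- 1 / length(members)
    }
    grand <- rowMeans(vQc)
    if (any(grand <= 0))
        stop("feature(s) with all-zero QC signal: ",
             paste(utils::head(rownames(x)[grand <= 0], 5), collapse = ", "))
    (vQc %*% t(W)) / grand
}

#' Local-mean (lomec) normalization factors
#'
#' Feature-based signal correction from a sliding local mean: for feature
#' i and run j, the factor is the mean of feature i over the `windowK` QC
#' runs nearest to j in injection index (ties broken toward earlier
#' injections), divided by feature i's grand QC mean.  With `windowK`
#' equal to the number of QC runs the factors are all unity.
#'
#' @param x a complete [AdductExperiment-class]
#' @param windowK number of QC runs in the local window (>= 2)
#' @param qcTypes run types supplying QC intensities
#' @return features x runs matrix of positive factors.
#' @export
lomecFactors <- function(x, windowK = 4L,
                         qcTypes = c("iqc", "tech_replicate")) {
    .checkComplete(x)
    if (windowK < 2) stop("windowK must be >= 2")
    qc <- .qcMask(x, qcTypes)
    if (sum(qc) < windowK)
        stop("need at least windowK = ", windowK, " QC runs")
    vQc <- peakAreas(x)[, qc, drop = FALSE]
    qcIdx <- injectionIndex(x)[qc]
    allIdx <- injectionIndex(x)
    W <- matrix(0, ncol(x), sum(qc))
    for (j in seq_len(ncol(x))) {
        near <- order(abs(qcIdx - allIdx[j]), qcIdx)[seq_len(windowK)]
        W[j, near] <- 1 / windowK
    }
    grand <- rowMeans(vQc)
    if (any(grand <= 0))
        stop("feature(s) with all-zero QC signal: ",
             paste(utils::head(rownames(x)[grand <= 0], 5), collapse = ", "))
    (vQc %*% t(W)) / grand
}

#' Linear-model-based signal correction (LMBSC)
#'
#' Per feature, ordinary least squares of QC intensity on injection index.
#' Only when the slope's two-sided t-test gives p < `alpha` is the feature
#' corrected: the factor at each run is the fitted line at that run's
#' injection index (clamped below at 1e-6 times the feature median, with a
#' warning) divided by the fitted value at the mean QC injection index;
#' otherwise the factors are unity.  The common divide-then-rescale step
#' follows.  With `alpha = 0` this is the identity; with `alpha = 1` every
#' feature is corrected.
#'
#' @param x a complete [AdductExperiment-class]
#' @param alpha significance level for the slope test
#' @param qcTypes run types supplying QC intensities (>= 3 runs required)
#' @return a [NormalizationResult-class] with method `"lmbsc"`.
#' @export
lmbscCorrect <- function(x, alpha = 0.05,
                         qcTypes = c("iqc", "tech_replicate")) {
    stopifnot(is(x, "AdductExperiment"))
    .checkComplete(x)
    qc <- .qcMask(x, qcTypes)
    n <- sum(qc)
    if (n < 3) stop("need at least 3 QC runs for LMBSC")
    Y <- peakAreas(x)[, qc, drop = FALSE]
    xi <- injectionIndex(x)[qc]
    xc <- xi - mean(xi)
    Sxx <- sum(xc^2)
    b1 <- as.vector(Y %*% xc) / Sxx             # slope per feature
    b0c <- rowMeans(Y)                          # fitted value at mean(xi)
    fitQc <- b0c + outer(b1, xc)
    rss <- rowSums((Y - fitQc)^2)
    se <- sqrt(rss / (n - 2) / Sxx)
    tstat <- b1 / se
    p <- 2 * pt(-abs(tstat), n - 2)
    p[is.nan(p)] <- 1                           # zero slope, zero residual
    sig <- p < alpha
    allIdx <- injectionIndex(x)
    factors <- matrix(1, nrow(x), ncol(x))
    if (any(sig)) {
        fitted <- b0c[sig] + outer(b1[sig], allIdx - mean(xi))
        ref <- b0c[sig]
        if (any(ref <= 0))
            stop("feature(s) with zero mean QC signal cannot be corrected")
        eps <- 1e-6 * apply(peakAreas(x)[sig, , drop = FALSE], 1, median)
        nClamp <- sum(fitted < eps)
        if (nClamp > 0)
            warning(nClamp,
                    " non-positive fitted value(s) clamped to epsilon")
        factors[sig, ] <- pmax(fitted, eps) / ref
    }
    res <- .applyFeatureFactors(x, factors, "lmbsc")
    metadata(res@corrected)$lmbscCorrectedFeatures <- rownames(x)[sig]
    res
}

#' Fit a LOESS curve with GCV-selected span
#'
#' Local polynomial regression (tricube weights) of intensity on injection
#' index, with the span chosen from a grid by minimizing generalized
#' cross-validation, GCV = n RSS / (n - tr(L))^2 with L the smoother
#' matrix.  The trace is computed exactly for n <= 200 points and by
#' loess's approximation above.  Prediction at arbitrary indices evaluates
#' the fitted local polynomial inside the fitted range and extends the
#' boundary fitted values as constants outside.
#'
#' @param x numeric injection indices (>= degree + 2 distinct values)
#' @param y numeric intensities
#' @param degree local polynomial degree, 1 or 2
#' @param spanGrid candidate spans in (0, 1]
#' @return object of class `LoessFit`: list with `span`, `degree`, `gcv`,
#'   `gcvGrid` (per-span scores), `fitted`, `x`, `model`.
#' @seealso [predictLoess()], [qcRlscCorrect()]
#' @export
loessGcvFit <- function(x, y, degree = 2L,
                        spanGrid = seq(0.2, 0.95, by = 0.05)) {
    if (length(unique(x)) < degree + 2)
        stop("need at least degree + 2 distinct x values")
    if (length(x) != length(y)) stop("x and y lengths differ")
    n <- length(y)
    exact <- n <= 200
    ctl <- loess.control(surface = "direct",
                         statistics = if (exact) "exact" else "approximate",
                         trace.hat = if (exact) "exact" else "approximate")
    gcvGrid <- rep(NA_real_, length(spanGrid))
    fits <- vector("list", length(spanGrid))
    df <- data.frame(x = x, y = y)
    for (s in seq_along(spanGrid)) {
        fit <- tryCatch(suppressWarnings(
            loess(y ~ x, data = df, span = spanGrid[s], degree = degree,
                  family = "gaussian", control = ctl)),
            error = function(e) NULL)
        if (is.null(fit)) next
        tr <- fit$trace.hat
        if (!is.finite(tr) || tr >= n) next
        rss <- sum(fit$residuals^2)
        gcvGrid[s] <- n * rss / (n - tr)^2
        fits[[s]] <- fit
    }
    if (all(is.na(gcvGrid)))
        stop("no candidate span produced a valid LOESS fit")
    best <- which.min(gcvGrid)
    structure(list(span = spanGrid[best], degree = degree,
                   gcv = gcvGrid[best],
                   gcvGrid = setNames(gcvGrid, spanGrid),
                   fitted = fits[[best]]$fitted, x = x,
                   model = fits[[best]]),
              class = "LoessFit")
}

#' Evaluate a fitted LOESS curve
#'
#' Evaluates the local polynomial inside the fitted x-range; outside, the
#' boundary fitted values are extended as constants.
#'
#' @param fit a `LoessFit` from [loessGcvFit()]
#' @param newx numeric evaluation points
#' @return numeric fitted values at `newx`.
#' @export
predictLoess <- function(fit, newx) {
    stopifnot(inherits(fit, "LoessFit"))
    xc <- pmin(pmax(newx, min(fit$x)), max(fit$x))
    as.numeric(predict(fit$model, newdata = data.frame(x = xc)))
}

#' @export
print.LoessFit <- function(x, ...) {
    cat(sprintf("LoessFit: degree %d, span %.2f (GCV %.4g), %d points\n",
                x$degree, x$span, x$gcv, length(x$x)))
    invisible(x)
}

#' QC-based robust LOESS signal correction (QC-RLSC)
#'
#' Per feature, a LOESS curve with GCV-selected span is fitted to the QC
#' intensities against injection index; the normalization factor at every
#' run is the fitted curve evaluated at that run's injection index
#' (clamped below at 1e-6 times the feature median), followed by the
#' common divide-then-rescale step.
#'
#' @param x a complete [AdductExperiment-class]
#' @param degree,spanGrid see [loessGcvFit()]
#' @param qcTypes run types supplying QC intensities (>= 5 runs required)
#' @return a [NormalizationResult-class] with method `"qc_rlsc"`.
#' @export
qcRlscCorrect <- function(x, degree = 2L,
                          spanGrid = seq(0.2, 0.95, by = 0.05),
                          qcTypes = c("iqc", "tech_replicate")) {
    stopifnot(is(x, "AdductExperiment"))
    .checkComplete(x)
    qc <- .qcMask(x, qcTypes)
    if (sum(qc) < 5) stop("need at least 5 QC runs for QC-RLSC")
    qcIdx <- injectionIndex(x)[qc]
    allIdx <- injectionIndex(x)
    v <- peakAreas(x)
    vQc <- v[, qc, drop = FALSE]
    factors <- matrix(NA_real_, nrow(x), ncol(x))
    nClamp <- 0L
    for (i in seq_len(nrow(x))) {
        fit <- loessGcvFit(qcIdx, vQc[i, ], degree = degree,
                           spanGrid = spanGrid)
        f <- predictLoess(fit, allIdx)
        eps <- 1e-6 * median(v[i, ])
        nClamp <- nClamp + sum(f < eps)
        factors[i, ] <- pmax(f, eps)
    }
    if (nClamp > 0)
        warning(nClamp, " non-positive fitted value(s) clamped to epsilon")
    res <- .applyFeatureFactors(x, factors, "qc_rlsc")
    metadata(res@corrected)$qcRlscClampedCells <- nClamp
    res
}

.batchAlignScale <- function(x, qcTypes) {
    batches <- unique(runBatch(x))
    if (length(batches) < 2) {
        warning("fewer than 2 batches; returning input unchanged")
        return(NULL)
    }
    qc <- .qcMask(x, qcTypes)
    v <- peakAreas(x)
    mB <- vapply(batches, function(b) {
        inB <- qc & runBatch(x) == b
        if (!any(inB)) stop("batch ", b, " contains no QC run")
        rowMeans(v[, inB, drop = FALSE])
    }, numeric(nrow(v)))
    mB <- matrix(mB, nrow = nrow(v), dimnames = list(rownames(v), batches))
    if (any(mB <= 0)) stop("batch with zero QC mean response")
    grand <- rowMeans(mB)
    grand / mB[, match(runBatch(x), batches), drop = FALSE]
}

#' Between-batch alignment by mean QC response
#'
#' Per feature, each batch's runs are scaled by the ratio of the grand
#' mean (over batches) of per-batch QC means to that batch's QC mean, so
#' all batches share the same mean QC response.  Applied after
#' within-batch normalization.  With a single batch the input is returned
#' unchanged with a warning.
#'
#' @param object an [AdductExperiment-class] or a
#'   [NormalizationResult-class]; for the latter the alignment is folded
#'   into the stored factor surface so the divide-then-rescale round trip
#'   keeps reconstructing the raw data
#' @param qcTypes run types supplying the batch QC means
#' @param ... unused
#' @return same class as `object`.
#' @rdname batchAlignMean
#' @export
setMethod("batchAlignMean", "AdductExperiment",
          function(object, qcTypes = c("iqc", "tech_replicate"), ...) {
    .checkComplete(object)
    S <- .batchAlignScale(object, qcTypes)
    if (is.null(S)) return(object)
    assay(object, "peakArea") <- peakAreas(object) * S
    object
})

#' @rdname batchAlignMean
#' @export
setMethod("batchAlignMean", "NormalizationResult",
          function(object, qcTypes = c("iqc", "tech_replicate"), ...) {
    x <- object@corrected
    S <- .batchAlignScale(x, qcTypes)
    if (is.null(S)) return(object)
    assay(x, "peakArea") <- peakAreas(x) * S
    f <- object@factors
    if (!is.matrix(f)) {
        f <- matrix(f, nrow(x), ncol(x), byrow = TRUE)
        object@rescale <- rep(object@rescale, nrow(x))
    }
    f <- f / S
    dimnames(f) <- dimnames(x)
    new("NormalizationResult", corrected = x, factors = f,
        method = object@method, rescale = object@rescale)
})
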