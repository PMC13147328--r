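#' Remove features with too many missing sample runs
#'
#' A feature is removed iff its fraction of missing cells *among sample
#' runs* exceeds `maxMissingFraction` (strict inequality: a feature missing
#' in exactly half of the sample runs is kept at the default 0.5).  QC runs
#' never enter the fraction.  Filtering precedes imputation.
#'
#' @param x an [AdductExperiment-class] with at least one sample run
#' @param maxMissingFraction maximum tolerated missing fraction (default
#'   0.5)
#' @return the filtered [AdductExperiment-class]; the ids of removed
#'   features are recorded in `metadata(.)$removedFeatures`.
#' @export
filterMissing <- function(x, maxMissingFraction = 0.5) {
    stopifnot(is(x, "AdductExperiment"))
    samp <- runType(x) == "sample"
    if (!any(samp)) stop("no sample runs in the table")
    frac <- rowMeans(is.na(peakAreas(x)[, samp, drop = FALSE]))
    drop <- frac > maxMissingFraction
    out <- x[!drop, ]
    metadata(out)$removedFeatures <- rownames(x)[drop]
    out
}

#' Impute missing cells from a half-minimum uniform distribution
#'
#' Each missing cell of feature i is replaced by an independent draw from
#' Uniform(min_i / 2, min_i), where min_i is the smallest observed value of
#' that feature across *all* runs (samples and QCs).  Observed cells are
#' never altered.  Draws are seeded and reproducible; the caller's RNG
#' state is restored on exit.
#'
#' @param x an [AdductExperiment-class]; every feature must have at least
#'   one observed value (apply [filterMissing()] first)
#' @param seed integer seed for the imputation draws
#' @return the completed [AdductExperiment-class]
#' @export
imputeHalfMin <- function(x, seed = 1L) {
    stopifnot(is(x, "AdductExperiment"))
    v <- peakAreas(x)
    nMiss <- rowSums(is.na(v))
    if (any(nMiss == ncol(v)))
        stop("feature(s) with no observed values: ",
             paste(utils::head(rownames(v)[nMiss == ncol(v)], 5),
                   collapse = ", "), " (filter first)")
    if (sum(nMiss) == 0L) return(x)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed))
    for (i in which(nMiss > 0)) {
        mn <- min(v[i, ], na.rm = TRUE)
        v[i, is.na(v[i, ])] <- runif(nMiss[i], mn / 2, mn)
    }
    assay(x, "peakArea") <- v
    metadata(x)$imputedCells <- setNames(nMiss, rownames(v))[nMiss > 0]
    x
}

#' Correct sample runs for DNA amount
#'
#' Divides each sample run's peak areas by that run's DNA concentration
#' (ng/uL) and multiplies by the arithmetic mean concentration over sample
#' runs, so corrected values stay on the original intensity scale.  QC and
#' technical-replicate runs are pooled after extraction and are left
#' unchanged.
#'
#' @param x an [AdductExperiment-class]; every sample run must carry a
#'   positive `dnaConcentration`
#' @return the corrected [AdductExperiment-class]
#' @export
dnaConcCorrect <- function(x) {
    stopifnot(is(x, "AdductExperiment"))
    samp <- runType(x) == "sample"
    if (!any(samp)) stop("no sample runs in the table")
    conc <- dnaConcentration(x)[samp]
    if (anyNA(conc))
        stop("sample run(s) without DNA concentration: ",
             paste(utils::head(colnames(x)[samp][is.na(conc)], 5),
                   collapse = ", "))
    if (any(conc <= 0)) stop("DNA concentrations must be > 0")
    v <- peakAreas(x)
    v[, samp] <- sweep(v[, samp, drop = FALSE], 2, mean(conc) / conc, "*")
    assay(x, "peakArea") <- v
    x
}

#' PCA of a log2-transformed, centered and scaled table
#'
#' Transforms each feature by log2, mean-centers and scales it to unit
#' variance, then performs PCA with runs as observations (via singular
#' value decomposition).  Zero-variance features are dropped with a
#' message.  Component signs are fixed by making each component's
#' largest-magnitude loading positive, so results are reproducible across
#' platforms.
#'
#' @param x a complete (post-imputation) [AdductExperiment-class]; all
#'   values must be strictly positive
#' @param nComponents optional cap on the number of components returned
#' @return list with `scores` (runs x components), `varExplained`
#'   (fractions summing to <= 1) and `loadings` (features x components).
#' @export
pcaTransform <- function(x, nComponents = NULL) {
    stopifnot(is(x, "AdductExperiment"))
    v <- peakAreas(x)
    if (anyNA(v)) stop("table must be complete (impute first)")
    if (any(v <= 0)) stop("all values must be > 0 for the log2 transform")
    lv <- log2(v)
    sds <- apply(lv, 1, stats::sd)
    if (any(sds == 0)) {
        message("dropping ", sum(sds == 0), " zero-variance feature(s)")
        lv <- lv[sds > 0, , drop = FALSE]
    }
    z <- t(scale(t(lv)))    # per-feature center + unit variance
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    k <- if (is.null(nComponents)) ncol(pc$x)
         else min(nComponents, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    load <- pc$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {     # deterministic sign: top loading positive
        if (load[which.max(abs(load[, j])), j] < 0) {
            load[, j] <- -load[, j]
            scores[, j] <- -scores[, j]
        }
    }
    varExplained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    list(scores = scores, varExplained = varExplained, loadings = load)
}
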