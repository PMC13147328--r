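## run layout used by most normalization tests
normFixture <- function(seed = 1, ...) {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 30,
                                               nFeatures = 15, nIstd = 3,
                                               seed = seed, ...))
    imputeHalfMin(filterMissing(sim$experiment), seed)
}

allMethods <- c("none", "tic", "median", "fbsc_b", "lomec", "lmbsc",
                "qc_rlsc")

test_that("method none is the identity with unit factors", {
    x <- normFixture()
    res <- normalizeDrift(x, "none")
    expect_identical(peakAreas(correctedTable(res)), peakAreas(x))
    expect_true(all(normFactors(res) == 1))
    expect_identical(normMethod(res), "none")
})

test_that("every method is the identity on a constant table", {
    sim <- simulateAdductTable(nullNoiseConfig(nSamples = 30,
                                               nFeatures = 10, nIstd = 2,
                                               seed = 2))
    x <- sim$experiment
    for (m in allMethods) {
        res <- normalizeDrift(x, m)
        expect_relative_equal(peakAreas(correctedTable(res)),
                              peakAreas(x), 1e-9)
    }
})

test_that("divide-then-rescale round trip reconstructs the raw table", {
    x <- normFixture(seed = 5)
    raw <- peakAreas(x)
    for (m in allMethods) {
        res <- normalizeDrift(x, m)
        v <- peakAreas(correctedTable(res))
        f <- normFactors(res)
        r <- rescaleConstant(res)
        back <- if (is.matrix(f)) v * f / r
                else sweep(v, 2, f, "*") / r
        expect_relative_equal(back, raw, 1e-9)
        ## median of the applied (post-rescale) factors is exactly 1
        applied <- if (is.matrix(f)) f / r else f / r
        med <- if (is.matrix(applied)) apply(applied, 1, median)
               else median(applied)
        expect_relative_equal(med, rep(1, length(med)), 1e-9)
    }
})

test_that("TIC factors equalize run totals (hand-computed example)", {
    v <- cbind(c(2, 4, 6), c(1, 2, 3))
    x <- makeExperiment(v, c("sample", "sample"))
    f <- ticFactors(x)
    expect_equal(unname(f), c(12, 6))
    res <- normalizeDrift(x, "tic")
    expect_equal(unname(peakAreas(correctedTable(res))),
                 cbind(c(1.5, 3, 4.5), c(1.5, 3, 4.5)))
    ## proportional runs collapse to identical columns; equal totals = identity
    totals <- unname(colSums(peakAreas(correctedTable(res))))
    expect_equal(totals[1], totals[2])
})

test_that("median factors use run medians and resist outliers", {
    v <- cbind(c(5, 10, 15), c(10, 20, 30))
    x <- makeExperiment(v, c("sample", "sample"))
    f <- medianFactors(x)
    expect_equal(unname(f), c(10, 20))
    res <- normalizeDrift(x, "median")
    expect_equal(unname(peakAreas(correctedTable(res))[2, ]), c(15, 15))
    ## a huge outlier in one run moves TIC but not the median factor
    v2 <- rbind(v, c(1e6, 10))
    x2 <- makeExperiment(v2, c("sample", "sample"))
    expect_equal(unname(medianFactors(x2)), c(12.5, 15))
    expect_gt(ticFactors(x2)[1] / ticFactors(x)[1], 1000)
})

test_that("FBSC-B bracket factors follow the local/grand mean ratio", {
    ## runs: iqc pair, 2 samples, iqc pair; one feature
    types <- c("iqc", "tech_replicate", "sample", "sample", "iqc",
               "tech_replicate")
    v <- matrix(c(100, 100, 80, 80, 120, 120), 1)
    x <- makeExperiment(v, types)
    f <- fbscBFactors(x)
    ## samples bracketed by pairs (100,100) and (120,120): local mean 110,
    ## grand mean 110 -> unit factor
    expect_equal(unname(f[1, 3:4]), c(1, 1))
    ## QC runs use their own pair
    expect_equal(unname(f[1, 1]), 100 / 110)
    expect_equal(unname(f[1, 5]), 120 / 110)
    ## all QC values equal per feature -> identity
    v2 <- matrix(c(100, 100, 80, 90, 100, 100), 1)
    x2 <- makeExperiment(v2, types)
    res <- normalizeDrift(x2, "fbsc_b")
    expect_relative_equal(peakAreas(correctedTable(res)), peakAreas(x2),
                          1e-9)
})

test_that("FBSC-B corrects a step drift located at a QC pair", {
    ## step change halfway, coinciding with the middle iQC pair
    types <- c(rep("sample", 5), "iqc", "tech_replicate", rep("sample", 5),
               "iqc", "tech_replicate", rep("sample", 5), "iqc",
               "tech_replicate")
    n <- length(types)
    step <- ifelse(seq_len(n) <= 7, 1, 2)
    set.seed(1)
    v <- rbind(1000 * step * exp(rnorm(n, 0, 0.02)),
               500 * step * exp(rnorm(n, 0, 0.02)))
    x <- makeExperiment(v, types)
    res <- normalizeDrift(x, "fbsc_b")
    qcRsd <- function(tab) median(featureRsd(tab, c("iqc",
                                                    "tech_replicate")))
    expect_lt(qcRsd(correctedTable(res)), qcRsd(x))
})

test_that("lomec local means: limiting cases and drift reduction", {
    x <- normFixture(seed = 7)
    nQc <- sum(runType(x) %in% c("iqc", "tech_replicate"))
    ## windowK = all QCs reduces to unit factors
    f <- lomecFactors(x, windowK = nQc)
    expect_relative_equal(f, matrix(1, nrow(f), ncol(f)), 1e-12)
    expect_error(lomecFactors(x, windowK = 1), "windowK")
    ## strong linear drift, no technical noise: corrected ISTD spread
    ## shrinks by at least half
    sim <- simulateAdductTable(adductSimConfig(nSamples = 40,
                                               nFeatures = 10, nIstd = 3,
                                               blockSize = 4, techCv = 0,
                                               dnaConcCv = 0,
                                               driftAmplitudeRange = c(0, 0),
                                               driftSlopeRange = c(0.6, 0.6),
                                               seed = 8))
    xs <- imputeHalfMin(filterMissing(sim$experiment), 8)
    istd <- sim$truth@istdIds
    before <- median(featureRsd(xs, "sample")[istd])
    after <- median(featureRsd(correctedTable(
        normalizeDrift(xs, "lomec")), "sample")[istd])
    expect_lt(after, before * 0.5)
})

test_that("LMBSC corrects only significant linear trends", {
    ## flat QC signal: identity
    x <- normFixture(seed = 3, techCv = 0, driftAmplitudeRange = c(0, 0),
                     driftSlopeRange = c(0, 0))
    res <- lmbscCorrect(x)
    expect_relative_equal(peakAreas(correctedTable(res)), peakAreas(x),
                          1e-9)
    ## noiseless line 100 + 2 * index: corrected values have slope ~ 0
    types <- rep(c("sample", "iqc", "tech_replicate"), 8)
    idx <- seq_along(types)
    v <- rbind(100 + 2 * idx, 50 + 0 * idx)
    xl <- makeExperiment(v, types)
    resl <- lmbscCorrect(xl)
    vc <- peakAreas(correctedTable(resl))[1, ]
    slope <- coef(lm(vc ~ idx))[2]
    expect_lt(abs(slope), 1e-6)
    ## alpha = 0 is the identity; alpha = 1 corrects every feature
    x2 <- normFixture(seed = 4)
    res0 <- lmbscCorrect(x2, alpha = 0)
    expect_relative_equal(peakAreas(correctedTable(res0)), peakAreas(x2),
                          1e-12)
    res1 <- lmbscCorrect(x2, alpha = 1)
    corrected <- S4Vectors::metadata(correctedTable(res1))$lmbscCorrectedFeatures
    expect_identical(sort(corrected), sort(rownames(x2)))
})

test_that("normalization commutes with feature relabeling", {
    x <- normFixture(seed = 6)
    perm <- rev(seq_len(nrow(x)))
    xp <- x[perm, ]
    for (m in c("tic", "fbsc_b", "lmbsc")) {
        a <- peakAreas(correctedTable(normalizeDrift(x, m)))
        b <- peakAreas(correctedTable(normalizeDrift(xp, m)))
        expect_equal(b, a[perm, ], tolerance = 1e-12)
    }
})

test_that("batch alignment equalizes per-batch QC means", {
    ## two batches, one feature, QC means 100 and 200
    types <- c("iqc", "tech_replicate", "sample", "iqc", "tech_replicate",
               "sample")
    v <- matrix(c(90, 110, 100, 190, 210, 200), 1)
    x <- makeExperiment(v, types, batch = c(rep("B1", 3), rep("B2", 3)))
    xa <- batchAlignMean(x)
    ## scale factors grand/m_b = 150/100 and 150/200
    expect_equal(unname(peakAreas(xa)[1, ]),
                 c(135, 165, 150, 142.5, 157.5, 150))
    qcB1 <- mean(peakAreas(xa)[1, 1:2])
    qcB2 <- mean(peakAreas(xa)[1, 4:5])
    expect_equal(qcB1, qcB2)
    ## single batch: warning, unchanged
    x1 <- makeExperiment(v, types, batch = "B1")
    expect_warning(x1a <- batchAlignMean(x1), "fewer than 2 batches")
    expect_identical(peakAreas(x1a), peakAreas(x1))
})

test_that("batch alignment folds into the normalization factors", {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 24,
                                               nFeatures = 10, nIstd = 2,
                                               nBatches = 2,
                                               batchEffectSd = 0.5,
                                               seed = 19))
    x <- imputeHalfMin(filterMissing(sim$experiment), 19)
    raw <- peakAreas(x)
    for (m in c("tic", "qc_rlsc")) {
        res <- batchAlignMean(normalizeDrift(x, m))
        v <- peakAreas(correctedTable(res))
        back <- v * normFactors(res) / rescaleConstant(res)
        expect_relative_equal(back, raw, 1e-9)
    }
})

test_that("batch alignment shrinks batch separation on PC1", {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 30,
                                               nFeatures = 40,
                                               nBatches = 2,
                                               batchEffectSd = 0.5,
                                               seed = 23))
    x <- imputeHalfMin(filterMissing(sim$experiment), 23)
    sil1 <- function(tab) {
        pc1 <- pcaTransform(tab)$scores[, 1]
        lab <- runBatch(tab)
        d <- abs(outer(pc1, pc1, "-"))
        mean(vapply(seq_along(pc1), function(i) {
            a <- mean(d[i, lab == lab[i] & seq_along(pc1) != i])
            b <- mean(d[i, lab != lab[i]])
            (b - a) / max(a, b)
        }, numeric(1)))
    }
    expect_lt(sil1(batchAlignMean(x)), sil1(x))
})
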