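test_that("missingness filter counts sample runs only, strict boundary", {
    types <- c(rep("sample", 10), "iqc", "tech_replicate", "eqc")
    v <- matrix(100, 4, 13)
    v[1, 1:6] <- NA                      # 6/10 sample runs missing
    v[2, 1:5] <- NA                      # exactly 5/10
    v[3, 11:13] <- NA                    # only QC runs missing
    x <- makeExperiment(v, types)
    xf <- filterMissing(x)
    expect_identical(S4Vectors::metadata(xf)$removedFeatures, "FT01")
    expect_identical(rownames(xf), c("FT02", "FT03", "FT04"))
    ## idempotent
    xf2 <- filterMissing(xf)
    expect_identical(peakAreas(xf2), peakAreas(xf))
    expect_length(S4Vectors::metadata(xf2)$removedFeatures, 0)

    qcOnly <- makeExperiment(matrix(1, 1, 2), c("iqc", "eqc"))
    expect_error(filterMissing(qcOnly), "no sample runs")
})

test_that("half-minimum imputation is bounded, seeded, non-destructive", {
    v <- rbind(c(8, NA, 12, 9), c(4, 5, 6, 7))
    x <- makeExperiment(v, rep("sample", 4))
    xi <- imputeHalfMin(x, seed = 11)
    imp <- peakAreas(xi)[1, 2]
    expect_gte(imp, 4); expect_lte(imp, 8)
    expect_identical(peakAreas(xi)[, -2], peakAreas(x)[, -2])
    expect_identical(peakAreas(imputeHalfMin(x, seed = 11)),
                     peakAreas(xi))
    expect_false(identical(peakAreas(imputeHalfMin(x, seed = 12)),
                           peakAreas(xi)))
    ## no missing cells: identity
    expect_identical(peakAreas(imputeHalfMin(xi, seed = 1)),
                     peakAreas(xi))
    ## fully missing feature is an error
    v2 <- rbind(c(NA, NA), c(1, 2))
    expect_error(imputeHalfMin(makeExperiment(v2, rep("sample", 2)), 1),
                 "no observed values")
})

test_that("imputed cells stay within per-feature bounds on simulated data", {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 20,
                                               nFeatures = 40, lod = 1e5,
                                               missingSteepness = 1e-4,
                                               seed = 3))
    x <- filterMissing(sim$experiment)
    xi <- imputeHalfMin(x, seed = 4)
    raw <- peakAreas(x)
    filled <- peakAreas(xi)
    for (i in which(rowSums(is.na(raw)) > 0)) {
        mn <- min(raw[i, ], na.rm = TRUE)
        got <- filled[i, is.na(raw[i, ])]
        expect_true(all(got >= mn / 2 & got <= mn))
    }
})

test_that("DNA-concentration correction scales samples only", {
    v <- rbind(c(100, 100, 100), c(50, 80, 60))
    x <- makeExperiment(v, c("sample", "sample", "iqc"),
                        conc = c(50, 100, NA))
    xc <- dnaConcCorrect(x)
    ## mean 75: factors 1.5 and 0.75; iQC untouched
    expect_equal(peakAreas(xc)[, 1], c(150, 75), ignore_attr = TRUE)
    expect_equal(peakAreas(xc)[, 2], c(75, 60), ignore_attr = TRUE)
    expect_identical(peakAreas(xc)[, 3], peakAreas(x)[, 3])
    ## equal concentrations: identity
    xe <- makeExperiment(v, c("sample", "sample", "iqc"),
                         conc = c(60, 60, NA))
    expect_equal(peakAreas(dnaConcCorrect(xe)), peakAreas(xe))
    ## inverse: corrected * conc / mean(conc) reproduces the input
    back <- sweep(peakAreas(xc)[, 1:2], 2, c(50, 100) / 75, "*")
    expect_equal(back, peakAreas(x)[, 1:2])
    ## missing concentration on a sample is an error
    xm <- makeExperiment(v, c("sample", "sample", "iqc"),
                         conc = c(50, NA, NA))
    expect_error(dnaConcCorrect(xm), "without DNA concentration")
})

test_that("pcaTransform is orthogonal, complete, and sign-stable", {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 15,
                                               nFeatures = 20, seed = 8))
    x <- imputeHalfMin(sim$experiment, 1)
    p <- pcaTransform(x)
    expect_equal(sum(p$varExplained), 1, tolerance = 1e-9)
    gram <- crossprod(p$scores)
    expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
    ## duplicated run columns give identical score rows
    v <- peakAreas(x); v[, 2] <- v[, 1]
    colnames(v) <- NULL
    x2 <- makeExperiment(v, runType(x))
    p2 <- pcaTransform(x2)
    expect_equal(p2$scores[1, ], p2$scores[2, ], tolerance = 1e-8)
    ## value <= 0 is rejected
    v3 <- peakAreas(x); v3[1, 1] <- 0
    colnames(v3) <- NULL
    expect_error(pcaTransform(makeExperiment(v3, runType(x))), "log2")
})

test_that("uncorrected batches separate along PC1", {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 30,
                                               nFeatures = 50,
                                               nBatches = 2,
                                               batchEffectSd = 1,
                                               seed = 14))
    x <- imputeHalfMin(filterMissing(sim$experiment), 1)
    p <- pcaTransform(x)
    pc1 <- p$scores[, 1]
    lab <- runBatch(x)
    ## mean silhouette on PC1 is positive: batches form clusters
    d <- abs(outer(pc1, pc1, "-"))
    sil <- mean(vapply(seq_along(pc1), function(i) {
        a <- mean(d[i, lab == lab[i] & seq_along(pc1) != i])
        b <- mean(d[i, lab != lab[i]])
        (b - a) / max(a, b)
    }, numeric(1)))
    expect_gt(sil, 0)
})
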