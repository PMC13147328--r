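test_that("buildSequence follows the block design", {
    cfg <- adductSimConfig(nSamples = 20, blockSize = 10, nEqc = 4)
    runs <- buildSequence(cfg)
    ## 4 eQC + (10 samples + iQC pair) x 2 + 4 eQC
    expected <- c(rep("eqc", 4),
                  rep("sample", 10), "iqc", "tech_replicate",
                  rep("sample", 10), "iqc", "tech_replicate",
                  rep("eqc", 4))
    expect_identical(runs$run_type, expected)
    expect_identical(runs$injection_index, seq_len(32L))
    ## the technical replicate is always the second vial of its pair
    techPos <- which(runs$run_type == "tech_replicate")
    expect_identical(runs$run_type[techPos - 1], rep("iqc", 2))

    one <- buildSequence(adductSimConfig(nSamples = 10, nBatches = 1))
    expect_identical(unique(one$batch), "B1")

    expect_error(buildSequence(adductSimConfig(nSamples = 0)))
})

test_that("batches are contiguous near-equal spans", {
    runs <- buildSequence(adductSimConfig(nSamples = 40, nBatches = 3))
    sizes <- table(runs$batch)
    expect_length(sizes, 3)
    expect_lte(diff(range(sizes)), 1)
    ## contiguity: batch labels never interleave
    expect_identical(runs$batch, sort(runs$batch))
})

test_that("simulation is deterministic given the seed", {
    cfg <- adductSimConfig(nSamples = 15, nFeatures = 12, lod = 2e4,
                           seed = 33)
    a <- simulateAdductTable(cfg)
    b <- simulateAdductTable(cfg)
    expect_identical(peakAreas(a$experiment), peakAreas(b$experiment))
    expect_identical(a$truth@trueAbundance, b$truth@trueAbundance)
    expect_identical(a$truth@driftSurface, b$truth@driftSurface)
    c_ <- simulateAdductTable(cfg, seed = 34)
    expect_false(identical(peakAreas(a$experiment),
                           peakAreas(c_$experiment)))
})

test_that("null noise config gives constant columns and equal QCs", {
    sim <- simulateAdductTable(nullNoiseConfig(nSamples = 12,
                                               nFeatures = 6, nIstd = 2,
                                               seed = 5))
    v <- peakAreas(sim$experiment)
    expect_false(anyNA(v))
    spread <- apply(v, 1, function(r) diff(range(r)) / max(r))
    expect_lt(max(spread), 1e-12)
    ## ISTD truth rows constant even under full noise defaults
    sim2 <- simulateAdductTable(adductSimConfig(nSamples = 12,
                                                nFeatures = 6, nIstd = 2,
                                                seed = 6))
    ist <- sim2$truth@trueAbundance[sim2$truth@istdIds, ]
    expect_lt(max(apply(ist, 1, function(r) diff(range(r)))), 1e-8)
    ## with unit drift and zero tech noise, observed ISTD rows are constant
    sim3 <- simulateAdductTable(nullNoiseConfig(nSamples = 12,
                                                nFeatures = 6, nIstd = 2,
                                                biologicalCv = 0.4,
                                                seed = 7))
    vi <- peakAreas(sim3$experiment)[sim3$truth@istdIds, ]
    expect_lt(max(apply(vi, 1, function(r) diff(range(r)) / max(r))), 1e-12)
})

test_that("missingness is censoring-driven and monotone in the LOD", {
    fracs <- vapply(c(0, 1e4, 1e5, 1e6), function(lod) {
        sim <- simulateAdductTable(adductSimConfig(nSamples = 25,
                                                   nFeatures = 40,
                                                   lod = lod, seed = 21))
        mean(is.na(peakAreas(sim$experiment)))
    }, numeric(1))
    expect_false(is.unsorted(fracs))
    expect_gt(fracs[4], fracs[1])
    ## low-intensity cells vanish more often than high-intensity ones
    sim <- simulateAdductTable(adductSimConfig(nSamples = 25,
                                               nFeatures = 60, lod = 1e5,
                                               missingSteepness = 1e-4,
                                               seed = 22))
    v <- peakAreas(sim$experiment)
    mu <- rowMeans(sim$truth@trueAbundance)   # latent feature level
    missRate <- rowMeans(is.na(v))
    low <- mu < stats::quantile(mu, 0.25)
    expect_gt(mean(missRate[low]), mean(missRate[!low]))
})

test_that("truthDriftRsd recovers the configured biological CV", {
    sim <- simulateAdductTable(adductSimConfig(nSamples = 10000,
                                               nFeatures = 4, nIstd = 1,
                                               biologicalCv = 0.4,
                                               seed = 17))
    r <- truthDriftRsd(sim$truth, sim$experiment)
    expect_equal(unname(r["ISTD01"]), 0)
    nonIstd <- setdiff(names(r), "ISTD01")
    expect_true(all(abs(r[nonIstd] - 0.4) / 0.4 < 0.05))
    ## zero biological variation gives zero robust spread everywhere
    sim0 <- simulateAdductTable(adductSimConfig(nSamples = 30,
                                                nFeatures = 5,
                                                biologicalCv = 0,
                                                seed = 18))
    expect_true(all(truthDriftRsd(sim0$truth, sim0$experiment) == 0))
})
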