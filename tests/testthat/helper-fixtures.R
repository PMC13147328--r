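## shared fixture builders; everything is generated in code

makeRunData <- function(types, batch = "B1", conc = NULL) {
    n <- length(types)
    if (is.null(conc)) {
        conc <- rep(NA_real_, n)
        conc[types == "sample"] <- 50
    }
    data.frame(run_id = sprintf("R%03d", seq_len(n)),
               injection_index = seq_len(n), run_type = types,
               batch = rep_len(batch, n), dna_concentration = conc,
               stringsAsFactors = FALSE)
}

makeExperiment <- function(values, types, batch = "B1", conc = NULL,
                           mz = NULL, rt = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("FT%02d", seq_len(nrow(values)))
    nf <- nrow(values)
    feats <- data.frame(feature_id = rownames(values),
                        mz = if (is.null(mz)) seq(100, 200, length.out = nf)
                             else mz,
                        rt = if (is.null(rt)) seq(60, 600, length.out = nf)
                             else rt)
    AdductExperiment(values, makeRunData(types, batch, conc), feats)
}

## a small mixed-type table used across core tests
tinyExperiment <- function() {
    v <- rbind(c(10, 20, 30, 25, 22, 21),
               c(5, NA, 8, 12, 9, 7),
               c(100, 110, 90, 105, 95, 102))
    makeExperiment(v, c("eqc", "sample", "sample", "iqc", "tech_replicate",
                        "sample"))
}

## drift-free, noise-free configuration: every feature column is constant
nullNoiseConfig <- function(...) {
    args <- list(biologicalCv = 0, techCv = 0,
                 driftAmplitudeRange = c(0, 0),
                 driftPeriodRange = c(40, 110),
                 driftSlopeRange = c(0, 0), batchEffectSd = 0,
                 qcDilution = 1, dnaConcCv = 0, lod = 0)
    over <- list(...)
    args[names(over)] <- over
    do.call(adductSimConfig, args)
}

expect_relative_equal <- function(actual, expected, tol) {
    expect_true(max(abs(actual - expected) / pmax(abs(expected), 1e-300))
                <= tol)
}
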