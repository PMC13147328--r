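#' Create a simulator configuration
#'
#' Constructs a validated [AdductSimConfig-class].  The defaults encode a
#' pooled-QC untargeted LC-MS study: four external QCs bracketing the
#' sequence, an internal QC pair after every ten samples with the second
#' vial treated as a technical replicate, moderate biological variation,
#' 5\% multiplicative technical noise, feature-dependent sinusoid-plus-trend
#' drift, and pooled QCs diluted to 80\% of the average sample.  Drift
#' oscillation periods default to 40--110 injections; slower behaviour is
#' represented by the linear-trend component (see the methods vignette).
#'
#' @param nSamples number of biological sample runs
#' @param nFeatures number of features (including ISTDs)
#' @param nIstd number of internal-standard features (constant true level)
#' @param blockSize samples between internal QC pairs
#' @param nEqc external QCs at sequence start and again at the end
#' @param nBatches number of contiguous batches
#' @param biologicalCv log-scale SD of sample abundances
#' @param highBioFraction fraction of non-ISTD features whose biological
#'   variance is multiplied by `highBioMultiplier`
#' @param highBioMultiplier variance multiplier for the high-variance subset
#' @param techCv log-scale SD of multiplicative technical noise
#' @param driftAmplitudeRange,driftPeriodRange,driftSlopeRange per-feature
#'   drift parameter ranges: amplitude (unitless), oscillation period
#'   (injections), linear trend (total fractional change over the sequence)
#' @param batchEffectSd log-scale SD of per-feature per-batch offsets
#' @param qcDilution pooled-QC abundance relative to the mean sample
#' @param lod censoring level: cells vanish with probability
#'   `plogis(missingSteepness * (lod - value))`
#' @param missingSteepness logistic steepness of censoring
#' @param dnaConcMean,dnaConcCv lognormal mean (ng/uL) and CV of per-sample
#'   DNA concentration
#' @param intensityRange per-feature baseline intensity range (log-uniform)
#' @param seed integer RNG seed
#' @return an [AdductSimConfig-class]
#' @examples
#' cfg <- adductSimConfig(nSamples = 20, nFeatures = 50, seed = 7)
#' sim <- simulateAdductTable(cfg)
#' sim$experiment
#' @export
adductSimConfig <- function(nSamples = 50L, nFeatures = 200L, nIstd = 3L,
                            blockSize = 10L, nEqc = 4L, nBatches = 1L,
                            biologicalCv = 0.4, highBioFraction = 0,
                            highBioMultiplier = 10, techCv = 0.05,
                            driftAmplitudeRange = c(0.1, 0.3),
                            driftPeriodRange = c(40, 110),
                            driftSlopeRange = c(-0.15, 0.15),
                            batchEffectSd = 0, qcDilution = 0.8,
                            lod = 0, missingSteepness = 1e-3,
                            dnaConcMean = 50, dnaConcCv = 0.3,
                            intensityRange = c(1e4, 1e7), seed = 1L) {
    new("AdductSimConfig",
        nSamples = as.integer(nSamples), nFeatures = as.integer(nFeatures),
        nIstd = as.integer(nIstd), blockSize = as.integer(blockSize),
        nEqc = as.integer(nEqc), nBatches = as.integer(nBatches),
        biologicalCv = biologicalCv, highBioFraction = highBioFraction,
        highBioMultiplier = highBioMultiplier, techCv = techCv,
        driftAmplitudeRange = as.numeric(driftAmplitudeRange),
        driftPeriodRange = as.numeric(driftPeriodRange),
        driftSlopeRange = as.numeric(driftSlopeRange),
        batchEffectSd = batchEffectSd, qcDilution = qcDilution,
        lod = lod, missingSteepness = missingSteepness,
        dnaConcMean = dnaConcMean, dnaConcCv = dnaConcCv,
        intensityRange = as.numeric(intensityRange), seed = as.integer(seed))
}

#' Build the injection sequence for a configuration
#'
#' Lays out the run order of a pooled-QC study: `nEqc` external QCs, then
#' blocks of `blockSize` samples each followed by an internal QC pair whose
#' second vial is recorded as a technical replicate, then `nEqc` external
#' QCs.  A trailing partial sample block is also followed by an iQC pair.
#' Batches are contiguous spans of near-equal size; injection indices run
#' 1..N.
#'
#' @param config an [AdductSimConfig-class]
#' @return data.frame with columns `run_id`, `injection_index`, `run_type`,
#'   `batch`, `dna_concentration` (all `NA`; filled by the simulator).
#' @export
buildSequence <- function(config) {
    stopifnot(is(config, "AdductSimConfig"))
    validObject(config)
    n <- config@nSamples
    types <- rep("eqc", config@nEqc)
    left <- n
    while (left > 0) {
        take <- min(config@blockSize, left)
        types <- c(types, rep("sample", take), "iqc", "tech_replicate")
        left <- left - take
    }
    types <- c(types, rep("eqc", config@nEqc))
    N <- length(types)
    batch <- paste0("B", ceiling(seq_len(N) / N * config@nBatches))
    data.frame(run_id = sprintf("R%04d", seq_len(N)),
               injection_index = seq_len(N), run_type = types, batch = batch,
               dna_concentration = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate a feature table with known ground truth
#'
#' Generates a feature-by-run peak-area table with the statistical
#' structure a pooled-QC LC-MS study exhibits, together with the latent
#' truth needed for recovery tests.  The generative model, per feature i
#' and run j (injection index j of N):
#'
#' \itemize{
#'   \item baseline \eqn{\mu_i} drawn log-uniform over `intensityRange`;
#'   \item sample abundance \eqn{\mu_i \exp(\sigma_b Z)} with
#'     \eqn{\sigma_b} = `biologicalCv` (times
#'     \eqn{\sqrt{highBioMultiplier}} for the high-variance subset);
#'   \item pooled-QC abundance = `qcDilution` times the mean of that
#'     feature's realized sample abundances, identical in every QC run
#'     (iQC, technical replicate and eQC);
#'   \item ISTD abundance exactly \eqn{\mu_i} in every run;
#'   \item multiplicative drift
#'     \eqn{d_i(j) = 1 + a_i \sin(2\pi j / P_i + \phi_i) + s_i j / N},
#'     clipped below at 0.05, with \eqn{a_i, P_i, s_i} drawn from the
#'     configured ranges and random phase;
#'   \item per-feature per-batch lognormal factor (SD `batchEffectSd`);
#'   \item sample runs scaled by their DNA amount relative to the
#'     population mean (QCs are pooled after extraction and are not
#'     scaled);
#'   \item lognormal technical noise (SD `techCv`);
#'   \item censoring: a cell goes missing with probability
#'     `plogis(missingSteepness * (lod - value))`.
#' }
#'
#' Identical configurations (including `seed`) give bit-identical output.
#'
#' @param config an [AdductSimConfig-class]
#' @param seed optional integer overriding `config@seed`
#' @return list with elements `experiment` ([AdductExperiment-class]) and
#'   `truth` ([SimTruth-class]).
#' @export
simulateAdductTable <- function(config, seed = NULL) {
    stopifnot(is(config, "AdductSimConfig"))
    validObject(config)
    if (!is.null(seed)) config@seed <- as.integer(seed)
    runs <- buildSequence(config)
    N <- nrow(runs)
    nf <- config@nFeatures
    ni <- config@nIstd
    set.seed(config@seed)

    istdIds <- if (ni > 0) sprintf("ISTD%02d", seq_len(ni)) else character(0)
    fid <- c(istdIds, sprintf("FT%05d", seq_len(nf - ni)))
    isIstd <- seq_len(nf) <= ni

    mu <- exp(runif(nf, log(config@intensityRange[1]),
                    log(config@intensityRange[2])))
    bioSd <- rep(config@biologicalCv, nf)
    high <- integer(0)
    if (config@highBioFraction > 0 && nf > ni) {
        nHigh <- round(config@highBioFraction * (nf - ni))
        if (nHigh > 0) {
            high <- ni + sample.int(nf - ni, nHigh)
            bioSd[high] <- bioSd[high] * sqrt(config@highBioMultiplier)
        }
    }
    bioSd[isIstd] <- 0

    isSample <- runs$run_type == "sample"
    isQc <- !isSample
    nS <- sum(isSample)

    ## latent abundances (before drift / batch / noise)
    abundance <- matrix(0, nf, N, dimnames = list(fid, runs$run_id))
    abundance[, isSample] <- mu * exp(matrix(rnorm(nf * nS, 0, 1), nf, nS) *
                                      bioSd)
    qcLevel <- config@qcDilution * rowMeans(abundance[, isSample,
                                                      drop = FALSE])
    abundance[, isQc] <- qcLevel
    abundance[isIstd, ] <- mu[isIstd]

    ## feature-dependent multiplicative drift: sinusoid + linear trend
    amp <- runif(nf, config@driftAmplitudeRange[1],
                 config@driftAmplitudeRange[2])
    per <- runif(nf, config@driftPeriodRange[1], config@driftPeriodRange[2])
    pha <- runif(nf, 0, 2 * pi)
    slo <- runif(nf, config@driftSlopeRange[1], config@driftSlopeRange[2])
    jj <- runs$injection_index
    ang <- outer(2 * pi / per, jj) + pha   # phase recycles along rows
    drift <- 1 + amp * sin(ang) + outer(slo, jj / N)
    drift <- pmax(drift, 0.05)
    dimnames(drift) <- dimnames(abundance)

    ## per-feature per-batch offsets
    batches <- unique(runs$batch)
    bf <- matrix(exp(rnorm(nf * length(batches), 0, config@batchEffectSd)),
                 nf, length(batches), dimnames = list(fid, batches))
    batchSurface <- bf[, match(runs$batch, batches), drop = FALSE]

    ## per-sample DNA amounts (samples only; QCs pooled after extraction)
    sdlog <- sqrt(log(1 + config@dnaConcCv^2))
    mlog <- log(config@dnaConcMean) - sdlog^2 / 2
    conc <- exp(rnorm(nS, mlog, sdlog))
    runs$dna_concentration[isSample] <- conc
    dnaScale <- rep(1, N)
    dnaScale[isSample] <- conc / config@dnaConcMean

    noise <- matrix(exp(rnorm(nf * N, 0, config@techCv)), nf, N)
    observed <- abundance * drift * batchSurface *
        matrix(dnaScale, nf, N, byrow = TRUE) * noise

    ## intensity-dependent censoring: low values vanish more often
    pMiss <- stats::plogis(config@missingSteepness * (config@lod - observed))
    observed[matrix(runif(nf * N), nf, N) < pMiss] <- NA_real_

    feats <- data.frame(feature_id = fid,
                        mz = runif(nf, 70, 700),
                        rt = runif(nf, 30, 900), stringsAsFactors = FALSE)
    experiment <- AdductExperiment(observed, runs, feats)
    metadata(experiment)$highVarFeatures <- fid[high]
    truth <- new("SimTruth", trueAbundance = abundance, driftSurface = drift,
                 batchFactors = bf, istdIds = istdIds)
    list(experiment = experiment, truth = truth)
}

#' Robust RSD of the latent abundances over sample runs
#'
#' The RSD* a perfect drift/batch correction could achieve, computed per
#' feature from the simulator's noise-free abundances restricted to sample
#' runs.  ISTD features give exactly 0; for lognormal biological variation
#' with log-scale SD sigma the value approaches sigma for moderate sigma.
#'
#' @param truth a [SimTruth-class]
#' @param runMeta the run metadata data.frame (as from [buildSequence()])
#'   or an [AdductExperiment-class] whose columns match `truth`
#' @return named numeric vector of per-feature RSD* values.
#' @export
truthDriftRsd <- function(truth, runMeta) {
    stopifnot(is(truth, "SimTruth"))
    type <- if (is(runMeta, "AdductExperiment")) runType(runMeta)
            else as.data.frame(runMeta)$run_type
    if (length(type) != ncol(truth@trueAbundance))
        stop("run metadata does not match the truth matrix")
    samp <- truth@trueAbundance[, type == "sample", drop = FALSE]
    apply(samp, 1, function(v) {
        m <- median(v)
        if (m == 0) return(NA_real_)
        mad(v, constant = 1.4826) / abs(m)
    })
}
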