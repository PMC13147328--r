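.defaultWorkflowConfig <- function() {
    list(methods = c("none", "qc_rlsc"), maxMissingFraction = 0.5,
         rsdThreshold = 0.3, dratioThreshold = 0.5,
         qcTypes = c("iqc", "tech_replicate"), alpha = 0.05, windowK = 4,
         degree = 2, batchAlign = FALSE, dnaCorrect = FALSE,
         istdPattern = "^ISTD", plots = TRUE, seed = 1)
}

.readWorkflowConfig <- function(config) {
    if (is.character(config) && length(config) == 1) {
        config <- if (grepl("\\.json$", config, ignore.case = TRUE))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    out <- .defaultWorkflowConfig()
    out[names(config)] <- config
    out
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

## mean silhouette width of a two-group labelling on the first PCs
.groupSilhouette <- function(scores, labels) {
    if (length(unique(labels)) < 2) return(NA_real_)
    d <- as.matrix(stats::dist(scores))
    mean(vapply(seq_along(labels), function(i) {
        own <- labels == labels[i]
        a <- mean(d[i, own & seq_along(labels) != i])
        b <- min(tapply(d[i, !own], labels[!own], mean))
        if (is.nan(a)) 0 else (b - a) / max(a, b)
    }, numeric(1)))
}

#' Run the full preprocessing and evaluation workflow
#'
#' Executes, for each requested normalization method: missingness
#' filtering, half-minimum imputation, normalization, optional
#' between-batch mean-response alignment, optional DNA-concentration
#' correction, RSD*/D-ratio evaluation with threshold retention, and PCA;
#' then compares methods (Dunn's all-pairs test on the RSD* of features
#' passing the RSD* threshold, and -- when internal standards are present
#' -- the Durbin-Conover test on ISTD sample-run RSD* with ISTDs as
#' blocks), with Holm adjustment and star labels.  All outputs are written
#' under `outDir`; given an identical configuration and seed, all data
#' files are byte-identical across runs (timestamps appear only in
#' messages).
#'
#' @param config a list, or path to a YAML/JSON file, with any of:
#'   `simulate` (arguments to [adductSimConfig()]; mutually exclusive with
#'   `input`), `input` (paths `values`, `runs`, `features`), `methods`,
#'   `maxMissingFraction`, `rsdThreshold`, `dratioThreshold`, `qcTypes`,
#'   `alpha`, `windowK`, `degree`, `batchAlign`, `dnaCorrect`,
#'   `istdPattern`, `plots`, `seed`
#' @param outDir output directory (created if needed)
#' @return (invisibly) list with per-method `metrics`, the summary list,
#'   and `outDir`.
#' @export
runWorkflow <- function(config, outDir) {
    cfg <- .readWorkflowConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(outDir, "config_echo.yaml"))

    x0 <- .stage("load", {
        if (!is.null(cfg$simulate)) {
            simArgs <- cfg$simulate
            if (is.null(simArgs$seed)) simArgs$seed <- cfg$seed
            sim <- simulateAdductTable(do.call(adductSimConfig, simArgs))
            sim$experiment
        } else if (!is.null(cfg$input)) {
            readAdductTable(cfg$input$values, cfg$input$runs,
                            cfg$input$features)
        } else stop("config needs either 'simulate' or 'input'")
    })
    message(sprintf("[load] %d features x %d runs", nrow(x0), ncol(x0)))

    xf <- .stage("filter", filterMissing(x0, cfg$maxMissingFraction))
    removed <- metadata(xf)$removedFeatures
    writeLines(removed, file.path(outDir, "removed_features.txt"))
    message(sprintf("[filter] %d -> %d features (%d removed)", nrow(x0),
                    nrow(xf), length(removed)))

    xi <- .stage("impute", imputeHalfMin(xf, seed = cfg$seed))
    message(sprintf("[impute] %d cells imputed",
                    sum(metadata(xi)$imputedCells)))

    istd <- grep(cfg$istdPattern, rownames(xi), value = TRUE)
    counts <- list(); istdRsd <- list(); passRsd <- list()
    allMetrics <- list(); silh <- list()
    for (m in cfg$methods) {
        xm <- .stage(paste0("normalize/", m), {
            res <- normalizeDrift(xi, m, qcTypes = cfg$qcTypes,
                                  windowK = cfg$windowK, alpha = cfg$alpha,
                                  degree = cfg$degree)
            if (isTRUE(cfg$batchAlign) &&
                length(unique(runBatch(xi))) > 1)
                res <- batchAlignMean(res, qcTypes = cfg$qcTypes)
            correctedTable(res)
        })
        if (isTRUE(cfg$dnaCorrect))
            xm <- .stage(paste0("dna_correct/", m), dnaConcCorrect(xm))
        met <- .stage(paste0("evaluate/", m),
                      evaluateFeatures(xm, cfg$rsdThreshold,
                                       cfg$dratioThreshold))
        mdf <- as.data.frame(met)
        utils::write.csv(mdf, file.path(outDir,
                                        sprintf("metrics_%s.csv", m)),
                         row.names = FALSE)
        writeLines(retainedFeatures(met),
                   file.path(outDir, sprintf("retained_%s.txt", m)))
        pca <- .stage(paste0("pca/", m), pcaTransform(xm, nComponents = 5))
        sc <- data.frame(run_id = rownames(pca$scores),
                         run_type = runType(xm), batch = runBatch(xm),
                         pca$scores, check.names = FALSE)
        utils::write.csv(sc, file.path(outDir,
                                       sprintf("pca_scores_%s.csv", m)),
                         row.names = FALSE)
        qcLab <- ifelse(runType(xm) == "sample", "sample", "qc")
        silh[[m]] <- .groupSilhouette(pca$scores[, 1:2, drop = FALSE], qcLab)
        if (isTRUE(cfg$plots)) {
            .pcaScorePlot(sc, pca$varExplained,
                          file.path(outDir, sprintf("pca_%s.pdf", m)))
            adductomeMap(xm, met,
                         file.path(outDir, sprintf("adductome_map_%s.pdf",
                                                   m)))
        }
        counts[[m]] <- as.list(countRetained(met))
        passRsd[[m]] <- mdf$rsd_star[mdf$rsd_pass]
        if (length(istd) >= 1)
            istdRsd[[m]] <- featureRsd(xm, "sample")[istd]
        allMetrics[[m]] <- met
        message(sprintf("[evaluate/%s] retained %d of %d features", m,
                        counts[[m]]$nRetained, nrow(xm)))
    }

    comparisons <- list()
    if (length(cfg$methods) >= 2) {
        ok <- lengths(passRsd) >= 2
        if (sum(ok) >= 2) {
            dp <- .stage("compare/dunn", dunnAllPairs(passRsd[ok]))
            comparisons$dunn_rsd <- .pairTable(dp)
            utils::write.csv(comparisons$dunn_rsd,
                             file.path(outDir, "pvalues_dunn_rsd.csv"),
                             row.names = FALSE)
        }
        if (length(istd) >= 2) {
            blocks <- do.call(cbind, istdRsd)  # ISTDs x methods
            dc <- .stage("compare/durbin_conover", durbinConover(blocks))
            comparisons$durbin_conover_istd <- .pairTable(dc)
            utils::write.csv(comparisons$durbin_conover_istd,
                             file.path(outDir, "pvalues_durbin_conover.csv"),
                             row.names = FALSE)
        }
    } else message("[compare] fewer than 2 methods; comparisons skipped")

    summary <- list(
        methods = cfg$methods,
        n_features_input = nrow(x0), n_features_filtered = nrow(xf),
        n_removed = length(removed),
        retained_counts = counts,
        istd_median_sample_rsd = lapply(istdRsd, function(v)
            if (length(v)) unname(median(v)) else NULL),
        qc_sample_silhouette = silh)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(metrics = allMetrics, summary = summary,
                   comparisons = comparisons, outDir = outDir))
}

## long-format pairwise p-value table with Holm adjustment and stars
.pairTable <- function(p) {
    idx <- which(upper.tri(p), arr.ind = TRUE)
    df <- data.frame(method_a = rownames(p)[idx[, 1]],
                     method_b = colnames(p)[idx[, 2]],
                     p_value = p[idx], stringsAsFactors = FALSE)
    df$p_holm <- holmAdjust(df$p_value)
    df$significance <- starLabels(df$p_holm)
    df[order(df$method_a, df$method_b), , drop = FALSE]
}

.pcaScorePlot <- function(scoreDf, varExplained, file) {
    p <- ggplot2::ggplot(scoreDf,
                         ggplot2::aes(x = PC1, y = PC2,
                                      colour = run_type,
                                      shape = batch)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * varExplained[1]),
                      y = sprintf("PC2 (%.1f%%)", 100 * varExplained[2])) +
        ggplot2::theme_bw()
    ggplot2::ggsave(file, p, width = 6, height = 4)
    invisible(file)
}

#' Adductome map of retained features
#'
#' Scatter of retained features in the retention-time / m/z plane, point
#' size proportional to the feature's median sample intensity.  With no
#' retained features, a warning file is written instead of a plot.
#'
#' @param x a complete [AdductExperiment-class]
#' @param metrics the matching [QcMetrics-class]
#' @param file output plot path (pdf)
#' @return the written file path, invisibly.
#' @export
adductomeMap <- function(x, metrics, file) {
    stopifnot(is(x, "AdductExperiment"), is(metrics, "QcMetrics"))
    keep <- rownames(x) %in% retainedFeatures(metrics)
    if (!any(keep)) {
        warning("no retained features; writing warning file")
        writeLines("no retained features to map",
                   paste0(file, ".warning.txt"))
        return(invisible(NULL))
    }
    xs <- x[keep, ]
    medInt <- apply(peakAreas(subsetRuns(xs, "sample")), 1, median,
                    na.rm = TRUE)
    df <- data.frame(rt = featureRt(xs), mz = featureMz(xs),
                     median_intensity = medInt)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = rt, y = mz,
                                          size = median_intensity)) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::scale_size_continuous(trans = "log10") +
        ggplot2::labs(x = "retention time (s)", y = "m/z (Da)",
                      size = "median sample\nintensity") +
        ggplot2::theme_bw()
    ggplot2::ggsave(file, p, width = 6, height = 4)
    invisible(file)
}
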