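## CSV/TSV schema:
##   values:   first column feature_id, remaining columns named by run_id
##   runs:     run_id, injection_index, run_type, batch, dna_concentration
##   features: feature_id, mz, rt
## Missing cells are empty strings or "NA" on disk and NA in memory; zero is
## a measured intensity, never missing.

.readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
                      na.strings = c("", "NA"), check.names = FALSE,
                      stringsAsFactors = FALSE)
}

#' Read a feature table from CSV/TSV files
#'
#' Reads the three-file on-disk representation of a feature table (peak
#' areas, run metadata, feature metadata) and returns a validated
#' [AdductExperiment-class].  Separator is inferred from the file extension
#' (`.tsv` = tab, anything else = comma).  Empty cells and the token `"NA"`
#' in the values file become missing cells.  Runs are ordered by
#' `injection_index` regardless of file order.
#'
#' @param valuesPath path to the values file: first column `feature_id`,
#'   remaining columns named by `run_id`
#' @param runMetaPath path to run metadata: columns `run_id`,
#'   `injection_index`, `run_type`, `batch`, optional `dna_concentration`
#' @param featureMetaPath path to feature metadata: columns `feature_id`,
#'   `mz`, `rt`
#' @return an [AdductExperiment-class]
#' @seealso [writeAdductTable()]
#' @export
readAdductTable <- function(valuesPath, runMetaPath, featureMetaPath) {
    values <- .readTable(valuesPath)
    runs <- .readTable(runMetaPath)
    feats <- .readTable(featureMetaPath)
    if (!"feature_id" %in% names(values))
        stop("values file must have a 'feature_id' column")
    if (anyDuplicated(values$feature_id))
        stop("duplicate feature_id in values file")
    m <- as.matrix(values[, setdiff(names(values), "feature_id"),
                          drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- values$feature_id
    AdductExperiment(m, runs, feats)
}

#' Write a feature table to CSV files
#'
#' Writes the three-file representation read back by [readAdductTable()];
#' the round trip is the identity on ids and run/feature metadata and
#' reproduces values within formatting precision (15 significant digits).
#' Missing cells are written as empty strings.
#'
#' @param x an [AdductExperiment-class] with at least one feature
#' @param outPrefix path prefix; files `<prefix>_values.csv`,
#'   `<prefix>_runs.csv` and `<prefix>_features.csv` are created
#' @return named character vector of the three paths, invisibly.
#' @export
writeAdductTable <- function(x, outPrefix) {
    stopifnot(is(x, "AdductExperiment"))
    if (nrow(x) == 0L)
        stop("refusing to write an empty feature set")
    dir.create(dirname(outPrefix), recursive = TRUE, showWarnings = FALSE)
    paths <- c(values = paste0(outPrefix, "_values.csv"),
               runs = paste0(outPrefix, "_runs.csv"),
               features = paste0(outPrefix, "_features.csv"))
    v <- peakAreas(x)
    vdf <- data.frame(feature_id = rownames(v),
                      format(v, digits = 15, trim = TRUE, scientific = TRUE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    vdf[-1][is.na(v)] <- ""
    ok <- try(utils::write.csv(vdf, paths["values"], row.names = FALSE,
                               quote = FALSE, na = ""), silent = TRUE)
    if (inherits(ok, "try-error"))
        stop("cannot write to ", paths["values"])
    runs <- data.frame(run_id = colnames(x),
                       injection_index = injectionIndex(x),
                       run_type = runType(x), batch = runBatch(x),
                       dna_concentration = dnaConcentration(x),
                       stringsAsFactors = FALSE)
    utils::write.csv(runs, paths["runs"], row.names = FALSE, na = "")
    feats <- data.frame(feature_id = rownames(x), mz = featureMz(x),
                        rt = featureRt(x), stringsAsFactors = FALSE)
    utils::write.csv(feats, paths["features"], row.names = FALSE, na = "")
    invisible(paths)
}

#' Read extracted-ion-chromatogram summaries
#'
#' Reads a plain CSV of EIC points with columns `run_id`, `target_id`,
#' `rt` (seconds), `mz` (Da), `intensity`, as consumed by the peak-picking
#' parameter advisor ([estimatePpm()], [estimatePeakwidth()]).  Points are
#' sorted by `rt` within each trace.
#'
#' @param path CSV path
#' @return data.frame of EIC points
#' @export
readEics <- function(path) {
    df <- .readTable(path)
    req <- c("run_id", "target_id", "rt", "mz", "intensity")
    if (!all(req %in% names(df)))
        stop("EIC file must have columns: ", paste(req, collapse = ", "))
    if (any(df$mz <= 0)) stop("EIC mz values must be > 0")
    if (any(df$intensity < 0)) stop("EIC intensities must be >= 0")
    df[order(df$target_id, df$run_id, df$rt), , drop = FALSE]
}
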