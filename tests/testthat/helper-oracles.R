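## independent oracles shared by the unit and acceptance tests

## Conover t statistic for one treatment pair of a rank matrix
dcStat <- function(r, i, j) {
    b <- nrow(r); k <- ncol(r)
    Rj <- colSums(r)
    A <- sum(r^2); C <- b * k * (k + 1)^2 / 4
    T1 <- (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / (A - C)
    den2 <- (A - C) * 2 * b / ((b - 1) * (k - 1)) * (1 - T1 / (b * (k - 1)))
    if (den2 <= 0) return(sign(Rj[i] - Rj[j]) * Inf)
    (Rj[i] - Rj[j]) / sqrt(den2)
}

## exhaustive within-block permutation p-value for pair (i, j)
dcPermOracle <- function(X, i, j) {
    r0 <- t(apply(X, 1, rank))
    t0 <- abs(dcStat(r0, i, j))
    perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (q in seq_along(v))
            for (p in perms(v[-q])) out[[length(out) + 1]] <- c(v[q], p)
        out
    }
    ap <- do.call(rbind, perms(seq_len(ncol(X))))
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(ap))), nrow(X))))
    hits <- 0L
    for (w in seq_len(nrow(idx))) {
        rp <- t(vapply(seq_len(nrow(X)),
                       function(bl) r0[bl, ap[idx[w, bl], ]],
                       numeric(ncol(X))))
        if (abs(dcStat(rp, i, j)) >= t0 - 1e-9) hits <- hits + 1L
    }
    hits / nrow(idx)
}

## sampled Gaussian elution peak
gaussTrace <- function(sigma = 3, center = 0, step = 0.5, span = 15,
                       amp = 1000, run = "r1", mz = 300) {
    rt <- seq(center - span, center + span, by = step)
    data.frame(run_id = run, target_id = "t1", rt = rt, mz = mz,
               intensity = amp * exp(-(rt - center)^2 / (2 * sigma^2)))
}
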