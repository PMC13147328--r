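#' Holm step-down adjustment of p-values
#'
#' Sorts the m p-values ascending and returns
#' `p'_(k) = max_{j <= k} min(1, (m - j + 1) p_(j))` in the original
#' order (the classical step-down procedure, as implemented by
#' [stats::p.adjust]).
#'
#' @param p numeric p-values in \[0, 1\]
#' @return adjusted p-values, element-wise >= the input and <= 1.
#' @examples
#' holmAdjust(c(0.04, 0.01, 0.03))   # 0.06 0.03 0.06
#' @export
holmAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "holm")
}

.rankWithinBlocks <- function(X) t(apply(X, 1, rank))

#' Durbin-Conover paired pairwise comparisons
#'
#' For a balanced complete block design (blocks x treatments), values are
#' ranked within blocks and treatments are compared pairwise through the
#' Conover statistic on rank sums,
#' \deqn{t = (R_i - R_j) / \sqrt{\frac{2b(A - C)}{(b-1)(k-1)}
#'       \left(1 - \frac{T_1}{b(k-1)}\right)}}
#' with \eqn{A} the sum of squared ranks, \eqn{C = bk(k+1)^2/4} and
#' \eqn{T_1} the Durbin statistic, referred to a t distribution on
#' \eqn{(b-1)(k-1)} degrees of freedom.  Being rank-based, the test is
#' invariant to strictly monotone transforms of the data.  P-values are
#' unadjusted; apply [holmAdjust()] separately.
#'
#' @param blockMatrix numeric matrix, rows = blocks, columns = treatments,
#'   no missing cells
#' @return symmetric matrix of two-sided unadjusted p-values (diagonal
#'   `NA`).
#' @export
durbinConover <- function(blockMatrix) {
    X <- as.matrix(blockMatrix)
    if (anyNA(X)) stop("incomplete blocks: only the balanced complete design is supported")
    b <- nrow(X); k <- ncol(X)
    if (b < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
    r <- .rankWithinBlocks(X)
    Rj <- colSums(r)
    A <- sum(r^2)
    C <- b * k * (k + 1)^2 / 4
    if (A == C) {   # all treatments tie in every block
        p <- matrix(1, k, k, dimnames = list(colnames(X), colnames(X)))
        diag(p) <- NA_real_
        return(p)
    }
    T1 <- (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / (A - C)
    df <- (b - 1) * (k - 1)
    denom2 <- (A - C) * 2 * b / df * (1 - T1 / (b * (k - 1)))
    p <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        d <- Rj[i] - Rj[j]
        pij <- if (denom2 <= 0) {
            ## perfect separation: the rank ordering is identical in every
            ## block; unequal rank sums are then maximally significant
            if (d == 0) 1 else 0
        } else 2 * pt(-abs(d) / sqrt(denom2), df)
        p[i, j] <- p[j, i] <- pij
    }
    p
}

#' Dunn's nonparametric all-pairs comparison
#'
#' Jointly ranks all observations (midranks for ties) and compares each
#' pair of groups through
#' \deqn{z = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'       \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'       \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values, unadjusted.  For two groups without
#' ties, z squared equals the Kruskal-Wallis H statistic.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values); names are used for the result's dimnames
#' @return symmetric matrix of two-sided unadjusted p-values (diagonal
#'   `NA`).
#' @export
dunnAllPairs <- function(groups) {
    if (!is.list(groups) || length(groups) < 2)
        stop("need at least 2 groups")
    if (any(lengths(groups) < 2))
        stop("each group needs at least 2 values")
    xall <- unlist(groups, use.names = FALSE)
    if (any(!is.finite(xall))) stop("values must be finite")
    g <- rep(seq_along(groups), lengths(groups))
    N <- length(xall)
    rk <- rank(xall)
    meanRank <- tapply(rk, g, mean)
    n <- lengths(groups)
    ties <- table(xall)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    varTerm <- N * (N + 1) / 12 - tieCorr
    k <- length(groups)
    nm <- if (!is.null(names(groups))) names(groups)
          else paste0("group", seq_len(k))
    p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        se <- sqrt(varTerm * (1 / n[i] + 1 / n[j]))
        pij <- if (se == 0) 1 else
            2 * pnorm(-abs((meanRank[i] - meanRank[j]) / se))
        p[i, j] <- p[j, i] <- pij
    }
    p
}

#' Significance star labels for p-values
#'
#' `"****"` below 1e-4, `"***"` below 0.001, `"**"` below 0.01, `"*"`
#' below 0.05, `"ns"` otherwise.
#'
#' @param p numeric p-values
#' @return character vector of labels.
#' @export
starLabels <- function(p) {
    as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
                     labels = c("****", "***", "**", "*", "ns"),
                     right = FALSE))
}
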