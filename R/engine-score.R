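#' Variance-component score-test engine
#'
#' A dearseq-style engine, simplified. For each gene, log2-CPM values
#' (TMM effective library sizes) are centered; with the centered condition
#' indicator x the score statistic is
#' \code{Q = (sum(y * x))^2 / (sigma2 * sum(x^2))} with \code{sigma2} the
#' residual variance of the two-group fit. The asymptotic p comes from
#' chi-square(1); with \code{nPerm > 0} a permutation p over label
#' reassignments is reported instead (all distinct reassignments enumerated
#' when there are at most 10,000, otherwise sampled using \code{seed}).
#'
#' @inheritParams runNBExact
#' @param nPerm number of label permutations (0 = asymptotic p, the
#'   default).
#' @param seed RNG seed used only when permutations are sampled.
#' @return a DEResultTable data.frame, attribute \code{engine =
#'   "score_test"}; attribute \code{n_perm_used} gives the number of
#'   distinct reassignments when permutation p-values were computed.
#' @export
runScoreTest <- function(de, nf = NULL, nPerm = 0, seed = 1L) {
    m <- countsMatrix(de)
    if (is.null(nf)) nf <- tmmFactors(m)
    idx <- .groupIndex(de)
    y <- cpm(m, nf, log = TRUE, prior = 0.5)
    x <- as.numeric(idx$grp == 2L)

    qObs <- .scoreStat(y, x, idx)
    lfc <- rowMeans(y[, idx$g2, drop = FALSE]) -
        rowMeans(y[, idx$g1, drop = FALSE])
    nPermUsed <- NULL
    if (nPerm > 0) {
        perms <- .labelPermutations(length(x), sum(x), nPerm, seed)
        nPermUsed <- ncol(perms)
        exceed <- integer(nrow(m))
        for (j in seq_len(ncol(perms))) {
            xp <- numeric(length(x)); xp[perms[, j]] <- 1
            idxP <- list(g1 = which(xp == 0), g2 = which(xp == 1),
                         grp = xp + 1)
            exceed <- exceed +
                (.scoreStat(y, xp, idxP)$Q >= qObs$Q - 1e-12)
        }
        # under enumeration the identity labelling is one of the columns,
        # so exceed >= 1 and the minimum achievable p is 1 / nPermUsed
        p <- if (attr(perms, "enumerated")) exceed / nPermUsed
             else (1 + exceed) / (1 + nPermUsed)
    } else {
        p <- stats::pchisq(qObs$Q, df = 1, lower.tail = FALSE)
    }
    p[qObs$degenerate] <- 1
    lfc[qObs$degenerate] <- 0
    res <- .engineResult(rownames(m), rowMeans(cpm(m, nf)), lfc, qObs$Q, p,
                         "score_test")
    if (!is.null(nPermUsed)) attr(res, "n_perm_used") <- nPermUsed
    res
}

.scoreStat <- function(y, x, idx) {
    xc <- x - mean(x)
    yc <- y - rowMeans(y)
    num <- (yc %*% xc)^2
    mu1 <- rowMeans(y[, idx$g1, drop = FALSE])
    mu2 <- rowMeans(y[, idx$g2, drop = FALSE])
    rss <- rowSums((y[, idx$g1, drop = FALSE] - mu1)^2) +
        rowSums((y[, idx$g2, drop = FALSE] - mu2)^2)
    s2 <- rss / (ncol(y) - 2L)
    degenerate <- s2 <= 1e-12
    Q <- as.numeric(num) / (pmax(s2, 1e-12) * sum(xc^2))
    Q[degenerate] <- 0
    list(Q = Q, degenerate = degenerate)
}

# distinct assignments of n2 "test" labels among m samples; columns are the
# indices receiving a test label. When enumeration is too large, sample.
.labelPermutations <- function(m, n2, nPerm, seed) {
    total <- choose(m, n2)
    if (total <= 10000) {
        cmb <- utils::combn(m, n2)
        attr(cmb, "enumerated") <- TRUE
        cmb
    } else {
        set.seed(seed)
        cmb <- replicate(nPerm, sort(sample.int(m, n2)))
        attr(cmb, "enumerated") <- FALSE
        cmb
    }
}
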