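#' NB exact-test engine
#'
#' A two-group negative-binomial exact test in the edgeR mold, simplified.
#' Counts are TMM-normalized and scaled to a common (geometric-mean)
#' effective library size; a common dispersion is estimated by maximizing
#' the conditional NB likelihood summed over genes; tagwise dispersions are
#' moment estimates shrunk toward the common value with \code{priorDf} prior
#' degrees of freedom; the p-value conditions on each gene's two group
#' totals, summing the probabilities of all outcomes no more likely than the
#' observed split (the same two-sided rule as \code{binom.test}, to which
#' the test reduces as dispersion approaches zero).
#'
#' @param de a filtered \linkS4class{DEExperiment}.
#' @param nf TMM \linkS4class{NormFactors}; computed if NULL.
#' @param priorDf prior degrees of freedom for tagwise shrinkage
#'   (default 10).
#' @return a DEResultTable data.frame (gene, base_mean, log2_fc, stat,
#'   p_value, padj), attribute \code{engine = "nb_exact"}.
#' @export
runNBExact <- function(de, nf = NULL, priorDf = 10) {
    m <- countsMatrix(de)
    if (is.null(nf)) nf <- tmmFactors(m)
    idx <- .groupIndex(de)
    eff <- effectiveLibSizes(nf)
    common <- exp(mean(log(eff)))
    adj <- t(t(m) * (common / eff))   # counts at a shared library size

    phiCommon <- .commonDispersion(adj, idx)
    phiTag <- .tagwiseDispersion(adj, idx, phiCommon, priorDf)

    z <- round(adj)
    z1 <- rowSums(z[, idx$g1, drop = FALSE])
    z2 <- rowSums(z[, idx$g2, drop = FALSE])
    n1 <- length(idx$g1); n2 <- length(idx$g2)
    p <- vapply(seq_len(nrow(m)), function(g)
        .nbExactPValue(z1[g], z2[g], n1, n2, phiTag[g]), numeric(1L))

    lfc <- .log2fcOfMeans(adj, idx$g1, idx$g2)
    stat <- sign(lfc) * stats::qnorm(pmax(p / 2, 1e-300), lower.tail = FALSE)
    res <- .engineResult(rownames(m), rowMeans(adj), lfc, stat, p, "nb_exact")
    attr(res, "dispersion") <- phiTag
    attr(res, "common_dispersion") <- phiCommon
    res
}

# conditional NB log-likelihood of one group with equal libraries; terms
# free of phi are dropped (safe: only differences in phi matter)
.condLogLik <- function(y, phi) {
    r <- 1 / phi
    n <- ncol(y)
    z <- rowSums(y)
    rowSums(lgamma(y + r)) + lgamma(n * r) - lgamma(z + n * r) -
        n * lgamma(r)
}

.commonDispersion <- function(adj, idx) {
    obj <- function(logPhi) {
        phi <- exp(logPhi)
        sum(.condLogLik(adj[, idx$g1, drop = FALSE], phi)) +
            sum(.condLogLik(adj[, idx$g2, drop = FALSE], phi))
    }
    stats::optimize(obj, interval = log(c(1e-6, 5)), maximum = TRUE,
                    tol = 1e-4)$maximum |> exp()
}

.tagwiseDispersion <- function(adj, idx, phiCommon, priorDf) {
    d <- ncol(adj) - 2L
    mom <- numeric(nrow(adj))
    for (g in list(idx$g1, idx$g2)) {
        y <- adj[, g, drop = FALSE]
        mu <- rowMeans(y)
        s2 <- .rowVars(y)
        ok <- mu > 0
        contrib <- numeric(nrow(adj))
        contrib[ok] <- pmax(0, (s2[ok] - mu[ok]) / mu[ok]^2)
        mom <- mom + contrib * (length(g) - 1L)
    }
    mom <- mom / (ncol(adj) - 2L)
    pmax((d * mom + priorDf * phiCommon) / (d + priorDf), 1e-8)
}

# Exact conditional two-sided p for group totals z1, z2 from n1 and n2
# samples sharing mean mu and dispersion phi. Sums P(k) over all splits k of
# z = z1 + z2 with P(k) <= P(z1); phi ~ 0 reduces to the binomial test.
.nbExactPValue <- function(z1, z2, n1, n2, phi) {
    z <- z1 + z2
    if (z == 0) return(1)
    if (phi < 1e-8)
        return(.minlikeP(stats::dbinom(0:z, z, n1 / (n1 + n2), log = TRUE),
                         z1 + 1L))
    mu <- z / (n1 + n2)
    s1 <- n1 / phi; mu1 <- n1 * mu
    s2 <- n2 / phi; mu2 <- n2 * mu
    if (z <= 5000) {
        k <- 0:z
    } else {
        lo <- max(stats::qnbinom(1e-13, size = s1, mu = mu1),
                  z - stats::qnbinom(1e-13, size = s2, mu = mu2,
                                     lower.tail = FALSE))
        hi <- min(stats::qnbinom(1e-13, size = s1, mu = mu1,
                                 lower.tail = FALSE),
                  z - stats::qnbinom(1e-13, size = s2, mu = mu2))
        lo <- max(0, min(lo, z1)); hi <- min(z, max(hi, z1))
        k <- lo:hi
    }
    lp <- stats::dnbinom(k, size = s1, mu = mu1, log = TRUE) +
        stats::dnbinom(z - k, size = s2, mu = mu2, log = TRUE)
    .minlikeP(lp, which(k == z1))
}

.minlikeP <- function(lp, iObs) {
    lp <- lp - max(lp)
    pr <- exp(lp)
    pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[iObs] * (1 + 1e-7)]))
}
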