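#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors. The reference sample is the
#' column whose upper-quartile count fraction is closest to the mean across
#' samples. For every other sample, per-gene log2 expression ratios (M) and
#' average log2 abundances (A) against the reference are computed over genes
#' positive in both; the M values are doubly trimmed (\code{logratioTrim} on
#' M, \code{absTrim} on A) and averaged with inverse asymptotic binomial
#' variance weights. Factors are rescaled so their geometric mean is 1.
#'
#' @param counts genes x samples count matrix.
#' @param logratioTrim fraction of M values trimmed at each end (default 0.30).
#' @param absTrim fraction of A values trimmed at each end (default 0.05).
#' @return a \linkS4class{NormFactors} with method "tmm".
#' @export
tmmFactors <- function(counts, logratioTrim = 0.30, absTrim = 0.05) {
    counts <- as.matrix(counts)
    lib <- colSums(counts)
    if (any(lib <= 0)) stop("every sample needs a positive library size")
    uq <- apply(counts, 2L, function(x) stats::quantile(x / sum(x), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        .tmmPair(counts[, j], lib[j], counts[, ref], lib[ref],
                 logratioTrim, absTrim,
                 sample = colnames(counts)[j])
    }, numeric(1L))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
    names(lib) <- colnames(counts)
    new("NormFactors", method = "tmm", factors = f, libSizes = lib)
}

# one sample vs the reference; mirrors the published TMM recipe
.tmmPair <- function(y, ly, yr, lr, logratioTrim, absTrim, sample = "?") {
    pos <- y > 0 & yr > 0
    if (!any(pos)) {
        warning("sample '", sample,
                "' shares no positive gene with the reference; factor set to 1")
        return(1)
    }
    p <- y[pos] / ly
    pr <- yr[pos] / lr
    M <- log2(p / pr)
    A <- 0.5 * log2(p * pr)
    w <- (ly - y[pos]) / (ly * y[pos]) + (lr - yr[pos]) / (lr * yr[pos])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratioTrim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * absTrim) + 1
    hiS <- n + 1 - loS
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
    if (!any(keep)) return(1)
    f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
    if (!is.finite(f)) f <- 0
    2^f
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor = median, over genes positive in every sample, of
#' the ratio of the sample's count to the gene's geometric-mean
#' pseudo-reference. Factors divide raw counts directly (no rescaling).
#'
#' @param counts genes x samples count matrix.
#' @return a \linkS4class{NormFactors} with method "median_of_ratios".
#' @export
medianOfRatios <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts <= 0) == 0L
    if (!any(allPos))
        stop("no gene has positive counts in every sample; ",
             "median-of-ratios is undefined (consider TMM)")
    logRef <- rowMeans(log(counts[allPos, , drop = FALSE]))
    sf <- apply(counts[allPos, , drop = FALSE], 2L, function(x)
        exp(stats::median(log(x) - logRef)))
    lib <- colSums(counts)
    names(sf) <- colnames(counts)
    names(lib) <- colnames(counts)
    new("NormFactors", method = "median_of_ratios", factors = sf,
        libSizes = lib)
}

#' Counts per million
#'
#' CPM of the effective library size, optionally log2 with a prior count:
#' \code{log2((count + prior) / (effLib + 2 * prior) * 1e6)}.
#'
#' @param counts genes x samples count matrix.
#' @param nf optional \linkS4class{NormFactors}; when NULL plain library
#'   sizes (column sums) are used.
#' @param log return log2-CPM.
#' @param prior prior count added on the log scale (default 0.5).
#' @return real matrix, same shape as \code{counts}.
#' @export
cpm <- function(counts, nf = NULL, log = FALSE, prior = 0.5) {
    counts <- as.matrix(counts)
    eff <- if (is.null(nf)) colSums(counts) else effectiveLibSizes(nf)
    if (any(eff <= 0)) stop("zero effective library size")
    if (log)
        t(log2((t(counts) + prior) / (eff + 2 * prior) * 1e6))
    else
        t(t(counts) / eff * 1e6)
}

#' Cook's distance screening for count outliers
#'
#' Per-gene, per-sample Cook's distances from the negative-binomial GLM fit
#' of the Wald engine: \code{D = r^2 / p * h / (1 - h)^2} with Pearson
#' residual \code{r = (y - mu) / sqrt(mu + phi * mu^2)}, \code{p = 2}
#' coefficients, and hat value \code{h} from the weighted two-group design.
#' Cells with \code{D} above the 99th percentile of \code{F(p, m - p)} are
#' flagged, never removed.
#'
#' @param counts genes x samples count matrix (raw).
#' @param mu fitted means matrix (same shape), from [runNBWald()].
#' @param dispersions per-gene NB dispersion vector.
#' @param condition two-level factor over samples.
#' @return list with matrix \code{D}, logical matrix \code{flagged}, and the
#'   \code{threshold}; or NULL (with a warning) when residual df <= 0.
#' @export
cooksDistance <- function(counts, mu, dispersions, condition) {
    m <- ncol(counts)
    p <- 2L
    if (m - p <= 0L) {
        warning("no residual degrees of freedom; Cook's screening skipped")
        return(NULL)
    }
    phi <- dispersions
    v <- mu + phi * mu^2
    r2 <- (counts - mu)^2 / pmax(v, 1e-12)
    w <- mu / (1 + phi * mu)          # GLM working weights, log link
    grp <- as.integer(condition)
    W1 <- rowSums(w[, grp == 1L, drop = FALSE])
    W2 <- rowSums(w[, grp == 2L, drop = FALSE])
    Wg <- cbind(W1, W2)[, grp, drop = FALSE]
    h <- w / pmax(Wg, 1e-12)          # hat values of the two-group fit
    h <- pmin(h, 1 - 1e-8)
    D <- r2 / p * h / (1 - h)^2
    thr <- stats::qf(0.99, p, m - p)
    list(D = D, flagged = D > thr, threshold = thr)
}
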