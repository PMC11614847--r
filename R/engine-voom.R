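#' Precision-weighted moderated-t engine
#'
#' A limma-voom style engine, simplified. log2-CPM values (prior count 0.5,
#' TMM effective library sizes) get per-observation precision weights from a
#' lowess trend of sqrt(residual sd) versus mean log2-CPM fitted on a first
#' unweighted pass; each gene is then fit by weighted two-group least
#' squares, the residual variances are moderated by empirical Bayes
#' (method-of-moments fit of a scaled-F model on the log variances), and a
#' moderated t with \code{d0 + (m - 2)} degrees of freedom is reported.
#'
#' @inheritParams runNBExact
#' @return a DEResultTable data.frame, attribute \code{engine = "voom_limma"};
#'   also carries attributes \code{s2} (residual variances), \code{s2post}
#'   (moderated variances), \code{d0} and \code{s02} (prior df and variance).
#' @export
runVoomT <- function(de, nf = NULL) {
    m <- countsMatrix(de)
    if (is.null(nf)) nf <- tmmFactors(m)
    idx <- .groupIndex(de)
    n1 <- length(idx$g1); n2 <- length(idx$g2)
    mTot <- n1 + n2
    d <- mTot - 2L
    stopifnot(d >= 1L)
    y <- cpm(m, nf, log = TRUE, prior = 0.5)

    # first pass: unweighted group means -> residual sd trend
    fit0 <- .weightedGroupFit(y, NULL, idx)
    s <- sqrt(fit0$s2)
    xbar <- rowMeans(y)
    ok <- is.finite(s) & s > 0
    if (sum(ok) >= 10) {
        lo <- stats::lowess(xbar[ok], sqrt(s[ok]), f = 0.5)
        trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    } else {
        trend <- function(x) rep(mean(sqrt(s[ok])), length(x))
    }
    fitted <- cbind(fit0$mu1, fit0$mu2)[, idx$grp, drop = FALSE]
    w <- matrix(1 / pmax(trend(fitted), 0.05)^4, nrow(y))

    fit <- .weightedGroupFit(y, w, idx)
    mod <- .moderateVariances(fit$s2, d)
    se <- sqrt(mod$s2post * (1 / fit$W1 + 1 / fit$W2))
    tstat <- fit$beta / se
    p <- 2 * stats::pt(-abs(tstat), df = mod$dfTotal)
    res <- .engineResult(rownames(m), rowMeans(cpm(m, nf)), fit$beta,
                         tstat, p, "voom_limma")
    attr(res, "s2") <- fit$s2
    attr(res, "s2post") <- mod$s2post
    attr(res, "d0") <- mod$d0
    attr(res, "s02") <- mod$s02
    res
}

# weighted (or unweighted) two-group least squares, vectorized over genes
.weightedGroupFit <- function(y, w, idx) {
    if (is.null(w)) w <- matrix(1, nrow(y), ncol(y))
    w1 <- w[, idx$g1, drop = FALSE]; w2 <- w[, idx$g2, drop = FALSE]
    y1 <- y[, idx$g1, drop = FALSE]; y2 <- y[, idx$g2, drop = FALSE]
    W1 <- rowSums(w1); W2 <- rowSums(w2)
    mu1 <- rowSums(w1 * y1) / W1
    mu2 <- rowSums(w2 * y2) / W2
    rss <- rowSums(w1 * (y1 - mu1)^2) + rowSums(w2 * (y2 - mu2)^2)
    d <- ncol(y) - 2L
    list(mu1 = mu1, mu2 = mu2, beta = mu2 - mu1, W1 = W1, W2 = W2,
         s2 = rss / d)
}

# empirical-Bayes variance moderation: fit s2 ~ s02 * F(d, d0) by
# method of moments on log(s2), then shrink
.moderateVariances <- function(s2, d) {
    ok <- is.finite(s2) & s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- if (sum(ok) > 1) stats::var(e) else 0
    rhs <- evar - trigamma(d / 2)
    if (is.finite(rhs) && rhs > 0) {
        d0 <- 2 * .trigammaInverse(rhs)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        s2post <- (d0 * s02 + d * s2) / (d0 + d)
    } else {
        # no detectable variance heterogeneity: infinite prior df; use the
        # unbiased pooled variance so equal inputs are a fixed point
        d0 <- Inf
        s02 <- mean(s2[ok])
        s2post <- rep(s02, length(s2))
    }
    s2post[!ok] <- s02
    list(s2post = pmax(s2post, 1e-12), d0 = d0, s02 = s02,
         dfTotal = if (is.finite(d0)) d0 + d else 1e6)
}

.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-8) break
    }
    y
}
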