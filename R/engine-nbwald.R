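#' NB Wald engine with trended dispersion shrinkage
#'
#' A DESeq2-style engine, simplified. Size factors come from
#' [medianOfRatios()]; per-gene dispersions are maximum-likelihood estimates
#' (vectorized two-stage grid search with group means refit in between); a
#' parametric trend \code{a0 + a1 / mu} is fit to the gene-wise estimates by
#' iteratively reweighted least squares; log-dispersions are shrunk toward
#' the log trend (maximum a posteriori under a normal prior whose variance
#' is the excess spread of the estimates around the trend), except for genes
#' more than 2 log2 units above the trend, which keep their own estimate.
#' The final NB GLM (log link, intercept + condition) yields a Wald z and a
#' two-sided p per gene.
#'
#' @inheritParams runNBExact
#' @param cooksFilter if TRUE, genes with any Cook's-flagged sample get
#'   \code{p_value = NA} (default FALSE: flags are reported only).
#' @return a DEResultTable data.frame, attribute \code{engine = "nb_wald"};
#'   also carries \code{dispersion} (MAP), \code{dispGeneEst} (MLE),
#'   \code{trendCoef} (a0, a1), \code{mu} (fitted means matrix), and
#'   \code{cooks} (output of [cooksDistance()]).
#' @export
runNBWald <- function(de, cooksFilter = FALSE) {
    m <- countsMatrix(de)
    idx <- .groupIndex(de)
    nf <- medianOfRatios(m)
    sf <- normFactors(nf)
    norm <- t(t(m) / sf)
    baseMean <- rowMeans(norm)

    phiMLE <- .dispGridMLE(m, sf, idx)
    trendFit <- .dispersionTrend(phiMLE, baseMean)
    phiTrend <- trendFit$fitted
    phiMAP <- .dispMAP(m, sf, idx, phiMLE, phiTrend,
                       df = ncol(m) - 2L)

    fit <- .nbIRLS(m, sf, idx, phiMAP)
    beta <- log(fit$q2) - log(fit$q1)          # natural-log scale
    mu <- cbind(fit$q1, fit$q2)[, idx$grp, drop = FALSE] *
        rep(sf, each = nrow(m))
    w <- mu / (1 + phiMAP * mu)
    W1 <- rowSums(w[, idx$g1, drop = FALSE])
    W2 <- rowSums(w[, idx$g2, drop = FALSE])
    se <- sqrt(1 / pmax(W1, 1e-12) + 1 / pmax(W2, 1e-12))
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))

    cooks <- cooksDistance(m, mu, phiMAP, conditions(de))
    if (cooksFilter && !is.null(cooks)) {
        flaggedGene <- rowSums(cooks$flagged) > 0L
        p[flaggedGene] <- NA_real_
    }
    res <- .engineResult(rownames(m), baseMean, beta / log(2), z, p,
                         "nb_wald")
    attr(res, "dispersion") <- phiMAP
    attr(res, "dispGeneEst") <- phiMLE
    attr(res, "trendCoef") <- trendFit$coef
    attr(res, "mu") <- mu
    attr(res, "cooks") <- cooks
    res
}

# vectorized IRLS for the two-group NB GLM with log link and size-factor
# offsets: mu_gj = sf_j * q_g,group(j). Newton steps on log q per group.
# Group means are floored at 0.125 normalized counts so an all-zero group
# still yields finite coefficients and standard errors.
.nbIRLS <- function(m, sf, idx, phi, floor = 0.125, iter = 30L) {
    fitGroup <- function(cols) {
        y <- m[, cols, drop = FALSE]
        s <- sf[cols]
        q <- pmax(rowMeans(t(t(y) / s)), floor)
        lq <- log(q)
        for (i in seq_len(iter)) {
            mu <- exp(lq) %o% s
            denom <- 1 + phi * mu
            score <- rowSums((y - mu) / denom)
            info <- rowSums(mu / denom)
            step <- score / pmax(info, 1e-10)
            step <- pmin(pmax(step, -3), 3)
            lq <- pmax(lq + step, log(floor))
            if (max(abs(step)) < 1e-10) break
        }
        exp(lq)
    }
    list(q1 = fitGroup(idx$g1), q2 = fitGroup(idx$g2))
}

# Cox-Reid adjusted profile log-likelihood at one dispersion value:
# penalizes by half the log-determinant of the information, which for the
# two-group design is log(W1) + log(W2). Removes most of the downward
# bias of the plain dispersion MLE.
.crLogLik <- function(m, mu, phi, idx) {
    mu <- pmax(mu, 1e-10)
    ll <- rowSums(stats::dnbinom(m, size = 1 / phi, mu = mu, log = TRUE))
    w <- mu / (1 + phi * mu)
    W1 <- rowSums(w[, idx$g1, drop = FALSE])
    W2 <- rowSums(w[, idx$g2, drop = FALSE])
    ll - 0.5 * (log(pmax(W1, 1e-12)) + log(pmax(W2, 1e-12)))
}

# two-stage vectorized grid MLE of the per-gene dispersion
.dispGridMLE <- function(m, sf, idx) {
    coarse <- exp(seq(log(1e-6), log(20), length.out = 40L))
    fit <- .nbIRLS(m, sf, idx, phi = rep(0.1, nrow(m)))
    mu <- cbind(fit$q1, fit$q2)[, idx$grp, drop = FALSE] *
        rep(sf, each = nrow(m))
    ll <- vapply(coarse, function(phi) .crLogLik(m, mu, phi, idx),
                 numeric(nrow(m)))
    best <- coarse[max.col(ll, ties.method = "first")]
    fit <- .nbIRLS(m, sf, idx, phi = best)
    mu <- cbind(fit$q1, fit$q2)[, idx$grp, drop = FALSE] *
        rep(sf, each = nrow(m))
    # refine one coarse step around the winner, per gene
    off <- seq(-0.45, 0.45, length.out = 19L)   # in coarse-grid log steps
    stepLog <- diff(log(coarse))[1L]
    phiFine <- exp(outer(log(best), off * 2 * stepLog, "+"))
    llFine <- matrix(0, nrow(m), length(off))
    for (j in seq_along(off))
        llFine[, j] <- .crLogLik(m, mu, phiFine[, j], idx)
    phi <- phiFine[cbind(seq_len(nrow(m)),
                         max.col(llFine, ties.method = "first"))]
    pmax(phi, 1e-8)
}

# parametric trend a0 + a1/mu by iteratively reweighted least squares with
# gamma-style weights and exclusion of far-off genes
.dispersionTrend <- function(phi, baseMean) {
    use <- baseMean > 1 & phi > 1e-6
    x <- 1 / baseMean[use]
    y <- phi[use]
    a <- c(stats::median(y), 0)
    for (it in 1:10) {
        f <- pmax(a[1] + a[2] * x, 1e-8)
        ratio <- y / f
        keep <- ratio > 1e-4 & ratio < 15
        w <- 1 / f[keep]^2
        X <- cbind(1, x[keep])
        co <- tryCatch(
            solve(crossprod(X * sqrt(w)), crossprod(X * w, y[keep])),
            error = function(e) matrix(a, 2L))
        aNew <- pmax(as.numeric(co), c(1e-6, 0))
        if (all(abs(aNew - a) < 1e-8 * (abs(a) + 1e-8))) { a <- aNew; break }
        a <- aNew
    }
    fitted <- pmax(a[1] + a[2] / baseMean, 1e-8)
    list(coef = c(a0 = a[1], a1 = a[2]), fitted = fitted)
}

# MAP shrinkage of log-dispersion toward the log trend
.dispMAP <- function(m, sf, idx, phiMLE, phiTrend, df) {
    lr <- log(phiMLE) - log(phiTrend)
    samplingVar <- trigamma(pmax(df, 1) / 2)
    priorVar <- max(stats::mad(lr)^2 - samplingVar, 0.25)
    fit <- .nbIRLS(m, sf, idx, phi = phiMLE)
    mu <- cbind(fit$q1, fit$q2)[, idx$grp, drop = FALSE] *
        rep(sf, each = nrow(m))
    grid <- seq(-3, 3, length.out = 41L)
    lpost <- matrix(0, nrow(m), length(grid))
    for (j in seq_along(grid)) {
        phi <- phiTrend * exp(grid[j])
        lpost[, j] <- .crLogLik(m, mu, phi, idx) -
            grid[j]^2 / (2 * priorVar)
    }
    phiMAP <- phiTrend * exp(grid[max.col(lpost, ties.method = "first")])
    outlier <- log2(phiMLE / phiTrend) > 2
    phiMAP[outlier] <- phiMLE[outlier]
    pmax(phiMAP, 1e-8)
}
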