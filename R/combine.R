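#' P-value combination methods
#'
#' Six ways to fuse k per-gene p-values (one per engine) into a single
#' combined p, plus helpers for the Max-P intersection, mean fold change,
#' BH adjustment and DE calling. All combiners map [0,1]^k to [0,1], are
#' symmetric in their inputs (Lancaster: given equal weights) and monotone
#' nondecreasing in each input. Inputs are clipped to
#' [1e-300, 1 - 1e-16] before any transform so every statistic is finite.
#'
#' \describe{
#'   \item{fisherCombine}{\code{X = -2 sum(log p)} against chi-square(2k).}
#'   \item{stoufferCombine}{\code{Z = sum(w z) / sqrt(sum(w^2))} with
#'     \code{z = qnorm(1 - p)}; a one-sided fusion of two-sided inputs.}
#'   \item{lancasterCombine}{\code{T = sum(qchisq(1 - p, df = w))} against
#'     chi-square(sum(w)); reduces to Fisher when every weight is 2.}
#'   \item{wilkinsonCombine}{the r-th smallest p against its Beta(r,
#'     k - r + 1) null.}
#'   \item{tippettCombine}{\code{1 - (1 - min p)^k}; Wilkinson with r = 1.}
#'   \item{bonferroniHolmCombine}{\code{min(1, min_i (k - i + 1) p_(i))}.}
#' }
#'
#' @param p numeric vector of p-values in [0,1] (one gene, k engines).
#' @return a single combined p-value in [0,1].
#' @rdname combiners
#' @export
fisherCombine <- function(p) {
    p <- .clipP(p)
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' @param w positive weights, recycled to length k (Stouffer default 1,
#'   Lancaster default 2).
#' @rdname combiners
#' @export
stoufferCombine <- function(p, w = 1) {
    p <- .clipP(p)
    w <- rep_len(w, length(p))
    z <- stats::qnorm(p, lower.tail = FALSE)
    stats::pnorm(sum(w * z) / sqrt(sum(w^2)), lower.tail = FALSE)
}

#' @rdname combiners
#' @export
lancasterCombine <- function(p, w = 2) {
    if (any(w <= 0)) stop("Lancaster weights must be positive")
    p <- .clipP(p)
    w <- rep_len(w, length(p))
    T <- sum(stats::qchisq(p, df = w, lower.tail = FALSE))
    stats::pchisq(T, df = sum(w), lower.tail = FALSE)
}

#' @param r which order statistic Wilkinson's method tests (default 1).
#' @rdname combiners
#' @export
wilkinsonCombine <- function(p, r = 1) {
    k <- length(p)
    if (r < 1 || r > k) stop("r must be in 1..k")
    if (r == 1) return(tippettCombine(p))  # closed form; exact identity
    p <- .clipP(p)
    stats::pbeta(sort(p)[r], r, k - r + 1)
}

#' @rdname combiners
#' @export
tippettCombine <- function(p) {
    p <- .clipP(p)
    1 - (1 - min(p))^length(p)
}

#' @rdname combiners
#' @export
bonferroniHolmCombine <- function(p) {
    p <- .clipP(p)
    k <- length(p)
    ps <- sort(p)
    min(1, min((k - seq_len(k) + 1) * ps))
}

.clipP <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    pmin(pmax(p, 1e-300), 1 - 1e-16)
}

# matrix versions, vectorized across genes (rows); NA rows handled upstream
.combineMatrix <- function(P, method, w = 2, r = 1) {
    P <- pmin(pmax(P, 1e-300), 1 - 1e-16)
    k <- ncol(P)
    switch(method,
        fisher = stats::pchisq(-2 * rowSums(log(P)), df = 2 * k,
                               lower.tail = FALSE),
        stouffer = {
            wv <- rep_len(w, k)
            Z <- as.numeric(stats::qnorm(P, lower.tail = FALSE) %*% wv) /
                sqrt(sum(wv^2))
            stats::pnorm(Z, lower.tail = FALSE)
        },
        lancaster = {
            wv <- rep_len(w, k)
            T <- rowSums(stats::qchisq(P, df = rep(wv, each = nrow(P)),
                                       lower.tail = FALSE))
            stats::pchisq(T, df = sum(wv), lower.tail = FALSE)
        },
        wilkinson = {
            if (r == 1) 1 - (1 - apply(P, 1L, min))^k
            else stats::pbeta(apply(P, 1L, function(x) sort(x)[r]),
                              r, k - r + 1)
        },
        tippett = 1 - (1 - apply(P, 1L, min))^k,
        bonferroni_holm = {
            mult <- k - seq_len(k) + 1
            pmin(1, apply(P, 1L, function(x) min(mult * sort(x))))
        },
        stop("unknown combiner: ", method))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; NA entries are excluded from the effective test
#' count and returned as NA.
#'
#' @param p numeric vector of p-values in [0,1] (NA allowed).
#' @return vector of adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0,1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' DE calling rule
#'
#' A gene is called DE iff \code{padj <= padjThr} and
#' \code{|log2FC| >= lfcThr} (both bounds inclusive).
#'
#' @param padj adjusted p-values.
#' @param log2fc log2 fold changes.
#' @param padjThr adjusted-p threshold (default 0.05).
#' @param lfcThr absolute log2FC threshold (default 1).
#' @return logical vector (NA padj gives FALSE).
#' @export
callDE <- function(padj, log2fc, padjThr = 0.05, lfcThr = 1) {
    stopifnot(padjThr > 0, padjThr < 1, lfcThr >= 0)
    out <- padj <= padjThr & abs(log2fc) >= lfcThr
    out[is.na(out)] <- FALSE
    out
}

#' Max-P intersection
#'
#' Genes called DE by all four engines (at the given thresholds), each
#' assigned the least significant (largest) of its raw engine p-values. An
#' empty intersection is a valid result.
#'
#' @param tables named list of the four engine DEResultTables (shared gene
#'   set and order).
#' @inheritParams callDE
#' @return data.frame with columns \code{gene}, \code{p_max} (possibly zero
#'   rows).
#' @export
maxPIntersect <- function(tables, padjThr = 0.05, lfcThr = 1) {
    core <- tables[intersect(.ENGINES, names(tables))]
    n <- nrow(core[[1L]])
    calls <- matrix(vapply(core, function(t)
        callDE(t$padj, t$log2_fc, padjThr, lfcThr), logical(n)), nrow = n)
    all4 <- rowSums(calls) == length(core)
    P <- matrix(vapply(core, function(t) t$p_value, numeric(n)), nrow = n)
    data.frame(gene = core[[1L]]$gene[all4],
               p_max = apply(P[all4, , drop = FALSE], 1L, max),
               stringsAsFactors = FALSE)
}

#' Mean log2 fold change across engines
#'
#' Arithmetic mean of the engines' log2 fold changes (the geometric mean of
#' the linear fold changes); sign discordance between engines is reported,
#' not resolved. A linear-scale mean is available via
#' \code{scale = "linear"}.
#'
#' @param tables named list of engine DEResultTables (shared gene order).
#' @param scale "log2" (default) or "linear".
#' @return data.frame with \code{gene}, \code{mean_log2_fc},
#'   \code{discordance} (number of engines whose nonzero log2FC sign
#'   disagrees with the majority).
#' @export
meanLog2FC <- function(tables, scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    core <- tables[intersect(.ENGINES, names(tables))]
    L <- matrix(vapply(core, function(t) t$log2_fc,
                       numeric(nrow(core[[1L]]))), nrow = nrow(core[[1L]]))
    mfc <- if (scale == "log2") rowMeans(L)
           else log2(rowMeans(2^L))
    npos <- rowSums(L > 0)
    nneg <- rowSums(L < 0)
    data.frame(gene = core[[1L]]$gene,
               mean_log2_fc = mfc,
               discordance = pmin(npos, nneg),
               stringsAsFactors = FALSE)
}

#' Combine engine results into the unified table
#'
#' Builds the combined per-gene output: mean log2FC, one combined p (plus
#' BH padj and DE call) per requested combiner, and the Max-P intersection
#' membership. Lancaster and Max-P are always included (the default
#' output). Genes for which fewer than two engines contribute a p-value
#' fall back to the single available p; their count is recorded in
#' \code{attr(, "single_engine_fallbacks")}.
#'
#' @param tables named list from [runAllEngines()] (at least the four core
#'   engines).
#' @param combiners character subset of \code{c("lancaster", "fisher",
#'   "stouffer", "wilkinson", "bonferroni_holm", "tippett")}.
#' @param lancasterWeights positive weights for Lancaster (default 2,
#'   which makes it coincide with Fisher).
#' @param wilkinsonR order statistic for Wilkinson (default 1 = Tippett).
#' @inheritParams callDE
#' @param fcScale forwarded to [meanLog2FC()].
#' @return data.frame: gene, mean_log2_fc, discordance, then
#'   \code{p_<m>}, \code{padj_<m>}, \code{call_<m>} per combiner, plus
#'   \code{max_p} (membership) and \code{p_max}.
#' @export
combineAll <- function(tables, combiners = c("lancaster"),
                       lancasterWeights = 2, wilkinsonR = 1,
                       padjThr = 0.05, lfcThr = 1,
                       fcScale = c("log2", "linear")) {
    fcScale <- match.arg(fcScale)
    combiners <- union("lancaster", combiners)
    known <- c("lancaster", "fisher", "stouffer", "wilkinson",
               "bonferroni_holm", "tippett")
    bad <- setdiff(combiners, known)
    if (length(bad)) stop("unknown combiner(s): ", paste(bad, collapse = ", "))
    core <- tables[intersect(.ENGINES, names(tables))]
    if (length(core) < 2L) stop("need at least two core engine tables")
    genes <- core[[1L]]$gene
    for (t in core) stopifnot(identical(t$gene, genes))
    P <- matrix(vapply(core, function(t) t$p_value, numeric(length(genes))),
                nrow = length(genes))

    out <- meanLog2FC(core, scale = fcScale)
    nAvail <- rowSums(!is.na(P))
    fallback <- sum(nAvail == 1L)
    full <- nAvail == ncol(P)
    singleP <- ifelse(nAvail == 1L, rowSums(P, na.rm = TRUE), NA_real_)

    for (m in combiners) {
        pc <- rep(NA_real_, length(genes))
        pc[full] <- .combineMatrix(P[full, , drop = FALSE], m,
                                   w = if (m == "lancaster") lancasterWeights
                                       else 1,
                                   r = wilkinsonR)
        part <- !full & nAvail >= 2L
        if (any(part)) pc[part] <- vapply(which(part), function(i) {
            pi <- P[i, !is.na(P[i, ])]
            switch(m,
                   lancaster = lancasterCombine(pi,
                       rep_len(lancasterWeights, length(pi))),
                   fisher = fisherCombine(pi),
                   stouffer = stoufferCombine(pi),
                   wilkinson = wilkinsonCombine(pi, min(wilkinsonR,
                                                        length(pi))),
                   bonferroni_holm = bonferroniHolmCombine(pi),
                   tippett = tippettCombine(pi))
        }, numeric(1L))
        pc[nAvail == 1L] <- singleP[nAvail == 1L]
        padj <- bhAdjust(pc)
        out[[paste0("p_", m)]] <- pc
        out[[paste0("padj_", m)]] <- padj
        out[[paste0("call_", m)]] <- callDE(padj, out$mean_log2_fc,
                                            padjThr, lfcThr)
    }
    mp <- maxPIntersect(core, padjThr, lfcThr)
    out$max_p <- out$gene %in% mp$gene
    out$p_max <- NA_real_
    out$p_max[match(mp$gene, out$gene)] <- mp$p_max
    if (fallback > 0)
        warning(fallback, " gene(s) had a single contributing engine; ",
                "their combined p is that engine's p")
    attr(out, "single_engine_fallbacks") <- fallback
    out
}
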