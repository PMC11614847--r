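#' Low-expression filters
#'
#' Three alternative gene filters applied before any engine runs. All three
#' return a subset of the input genes (original order preserved) and are
#' idempotent.
#'
#' \describe{
#'   \item{filterRowSums}{keep genes whose total count across all samples is
#'     at least \code{minTotal} (default 10).}
#'   \item{filterByExpression}{keep genes expressed at a worthwhile CPM level
#'     in at least as many samples as the smallest group, following the
#'     standard group-aware rule: the CPM cutoff is
#'     \code{minCount / median(library size in millions)}; the required
#'     sample count is the smallest group size, softened for large groups
#'     (\code{largeN + (n - largeN) * minProp} when the smallest group
#'     exceeds \code{largeN}); and the gene's total count must also reach
#'     \code{minTotal}.}
#'   \item{filterByVariance}{keep genes by variance of log2-CPM
#'     (prior count 0.5), either all genes with variance at least
#'     \code{minVariance} or the \code{topN} most variable (ties broken by
#'     gene identifier).}
#' }
#'
#' @param de a \linkS4class{DEExperiment}.
#' @param minTotal minimum total count over all samples.
#' @return the filtered \linkS4class{DEExperiment}.
#' @rdname filters
#' @export
filterRowSums <- function(de, minTotal = 10) {
    stopifnot(minTotal >= 0)
    keep <- rowSums(countsMatrix(de)) >= minTotal
    if (!any(keep))
        stop("all genes removed at minTotal = ", minTotal,
             "; lower the threshold")
    de[keep, ]
}

#' @param minCount count required (at the median library size) in enough
#'   samples, on the CPM scale.
#' @param largeN group size above which the required sample count is relaxed.
#' @param minProp proportion used in the large-group relaxation.
#' @rdname filters
#' @export
filterByExpression <- function(de, minCount = 10, minTotal = 15,
                               largeN = 10, minProp = 0.7) {
    m <- countsMatrix(de)
    lib <- colSums(m)
    n <- min(table(conditions(de)))
    if (n > largeN) n <- largeN + (n - largeN) * minProp
    cutoff <- minCount / stats::median(lib) * 1e6
    cpmM <- t(t(m) / lib) * 1e6
    tol <- 1e-14
    keep <- rowSums(cpmM >= cutoff) >= (n - tol) &
        rowSums(m) >= (minTotal - tol)
    if (!any(keep))
        stop("all genes removed by the expression filter")
    de[keep, ]
}

#' @param minVariance keep genes with log2-CPM variance >= this value
#'   (exclusive with \code{topN}).
#' @param topN keep the N most variable genes (exclusive with
#'   \code{minVariance}).
#' @rdname filters
#' @export
filterByVariance <- function(de, minVariance = NULL, topN = NULL) {
    if (is.null(minVariance) == is.null(topN))
        stop("supply exactly one of minVariance or topN")
    lc <- cpm(countsMatrix(de), log = TRUE)
    v <- .rowVars(lc)
    if (!is.null(minVariance)) {
        keep <- v >= minVariance
    } else {
        if (topN > nrow(de)) {
            warning("topN (", topN, ") exceeds gene count (", nrow(de),
                    "); keeping all genes")
            topN <- nrow(de)
        }
        ord <- order(-v, rownames(de))
        keep <- logical(nrow(de))
        keep[ord[seq_len(topN)]] <- TRUE
    }
    if (!any(keep))
        stop("all genes removed by the variance filter")
    de[keep, ]
}

.rowVars <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Dispatch a configured filter
#'
#' @param de a \linkS4class{DEExperiment}.
#' @param method one of "rowsums", "by_expression", "variance".
#' @param ... passed to the chosen filter.
#' @return filtered \linkS4class{DEExperiment}.
#' @export
applyFilter <- function(de, method = c("rowsums", "by_expression", "variance"),
                        ...) {
    method <- match.arg(method)
    switch(method,
           rowsums = filterRowSums(de, ...),
           by_expression = filterByExpression(de, ...),
           variance = filterByVariance(de, ...))
}
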