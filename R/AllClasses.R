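#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' DEExperiment: a two-condition count experiment
#'
#' Container for a genes x samples matrix of raw counts together with a
#' two-level condition factor defining the contrast. Extends
#' \linkS4class{SummarizedExperiment}; the first assay is named
#' \code{"counts"}, and \code{colData()$condition} holds the contrast factor.
#' The second factor level is the test class: its mean goes in the numerator
#' of every reported log2 fold change.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [DEExperiment()] for construction, [testLevel()],
#'   [referenceLevel()], [conditions()].
#' @exportClass DEExperiment
setClass("DEExperiment", contains = "SummarizedExperiment")

.validDEExperiment <- function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(m)))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
            if (any(m != round(m))) msg <- c(msg, "counts must be integral")
        }
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "gene identifiers must be present and unique")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "sample identifiers must be present and unique")
    }
    cond <- SummarizedExperiment::colData(object)$condition
    if (is.null(cond)) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        if (!is.factor(cond)) msg <- c(msg, "'condition' must be a factor")
        else {
            if (nlevels(cond) != 2L)
                msg <- c(msg, "'condition' must have exactly two levels")
            if (any(table(cond) < 2L))
                msg <- c(msg, "each condition level needs >= 2 samples")
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("DEExperiment", .validDEExperiment)

#' Construct a DEExperiment
#'
#' @param counts genes x samples matrix of nonnegative integer counts with
#'   unique row and column names.
#' @param condition factor (or coercible) of length \code{ncol(counts)}; must
#'   have exactly two levels with at least two samples each. The second level
#'   is the test class.
#' @param extra optional data.frame of additional per-sample covariates,
#'   carried in \code{colData} but ignored by all engines.
#' @return a validated \linkS4class{DEExperiment}.
#' @examples
#' m <- matrix(rpois(60, 20), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' de <- DEExperiment(m, rep(c("ctrl", "case"), each = 3))
#' testLevel(de)
#' @export
DEExperiment <- function(counts, condition, extra = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (!is.factor(condition))
        condition <- factor(condition, levels = unique(as.character(condition)))
    condition <- droplevels(condition)
    cd <- S4Vectors::DataFrame(condition = condition, row.names = colnames(counts))
    if (!is.null(extra)) {
        extra <- as.data.frame(extra)
        for (nm in setdiff(colnames(extra), "condition")) cd[[nm]] <- extra[[nm]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("DEExperiment", se)
}

#' Accessors for DEExperiment
#'
#' \code{conditions} returns the two-level condition factor,
#' \code{referenceLevel} and \code{testLevel} its first and second levels,
#' \code{countsMatrix} the raw count matrix.
#'
#' @param object a \linkS4class{DEExperiment}.
#' @return see description.
#' @rdname DEExperiment-accessors
#' @export
conditions <- function(object) SummarizedExperiment::colData(object)$condition

#' @rdname DEExperiment-accessors
#' @export
referenceLevel <- function(object) levels(conditions(object))[1L]

#' @rdname DEExperiment-accessors
#' @export
testLevel <- function(object) levels(conditions(object))[2L]

#' @rdname DEExperiment-accessors
#' @export
countsMatrix <- function(object) SummarizedExperiment::assay(object, "counts")

setMethod("show", "DEExperiment", function(object) {
    cond <- conditions(object)
    cat("DEExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  contrast:", testLevel(object), "(test) vs",
        referenceLevel(object), "(reference)\n")
    cat("  group sizes:", paste(table(cond), collapse = " / "), "\n")
})

#' NormFactors: per-sample normalization factors
#'
#' Holds the per-sample scaling factors produced by [tmmFactors()] (trimmed
#' mean of M-values; factors multiply library sizes into effective library
#' sizes and have geometric mean 1) or [medianOfRatios()] (size factors that
#' divide raw counts directly).
#'
#' @slot method "tmm" or "median_of_ratios".
#' @slot factors named positive numeric, one per sample.
#' @slot libSizes named numeric raw library sizes (column sums).
#' @exportClass NormFactors
setClass("NormFactors", representation(
    method = "character", factors = "numeric", libSizes = "numeric"))

setValidity("NormFactors", function(object) {
    msg <- character()
    if (!object@method %in% c("tmm", "median_of_ratios"))
        msg <- c(msg, "method must be 'tmm' or 'median_of_ratios'")
    if (any(!is.finite(object@factors)) || any(object@factors <= 0))
        msg <- c(msg, "all factors must be finite and > 0")
    if (length(object@factors) != length(object@libSizes))
        msg <- c(msg, "factors and libSizes lengths differ")
    if (object@method == "tmm" &&
        abs(mean(log(object@factors))) > 1e-9)
        msg <- c(msg, "tmm factors must have geometric mean 1")
    if (length(msg)) msg else TRUE
})

#' @rdname NormFactors-class
#' @param object a NormFactors object.
#' @export
normFactors <- function(object) object@factors

#' Effective library sizes
#'
#' For TMM, library size times factor; for median-of-ratios, the size factor
#' rescaled by the geometric-mean library size so that CPM values are on a
#' comparable per-million scale.
#'
#' @param object a \linkS4class{NormFactors}.
#' @return named numeric vector, one per sample.
#' @export
effectiveLibSizes <- function(object) {
    stopifnot(is(object, "NormFactors"))
    if (object@method == "tmm")
        object@libSizes * object@factors
    else
        object@factors * exp(mean(log(object@libSizes)))
}

setMethod("show", "NormFactors", function(object) {
    cat("NormFactors (", object@method, "): ",
        paste(sprintf("%s=%.4f", names(object@factors), object@factors),
              collapse = ", "), "\n", sep = "")
})
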