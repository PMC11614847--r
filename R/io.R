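#' Read a raw count matrix
#'
#' Reads a genes x samples table of nonnegative integer counts. The first
#' column holds gene identifiers, the header row sample identifiers. Row and
#' column order are preserved.
#'
#' @param path file path.
#' @param dialect "tsv" or "csv"; default guessed from the file extension
#'   (".csv" means csv, anything else tsv).
#' @return numeric matrix with unique dimnames.
#' @export
readCounts <- function(path, dialect = c("auto", "tsv", "csv")) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
    sep <- if (dialect == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = NA, comment.char = "")
    genes <- as.character(df[[1L]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        stop("duplicated gene identifier(s): ", paste(dup, collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        m <- matrix(suppressWarnings(as.numeric(m)), nrow = nrow(df),
                    dimnames = list(NULL, colnames(df)[-1L]))
    rownames(m) <- genes
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad)) {
        g <- rownames(m)[bad[1L, 1L]]
        s <- colnames(m)[bad[1L, 2L]]
        stop("count for gene '", g, "' in sample '", s,
             "' is not a nonnegative integer")
    }
    if (anyDuplicated(colnames(m)))
        stop("duplicated sample identifier(s) in header")
    storage.mode(m) <- "double"
    m
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]: writes genes in rows with a leading `gene`
#' column, so that reading the file back reproduces the matrix exactly.
#'
#' @param counts matrix with dimnames.
#' @param path output path.
#' @param dialect "tsv" or "csv".
#' @return the path, invisibly.
#' @export
writeCounts <- function(counts, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "csv") "," else "\t"
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet and fix the contrast
#'
#' Reads per-sample metadata, restricts it to the two requested condition
#' levels and returns a data.frame whose \code{condition} factor has the
#' contrast's first level as reference and second level as test class (the
#' test class mean goes in the log2FC numerator). Extra covariate columns are
#' carried through but ignored by the engines.
#'
#' @param path file path; first column = sample identifiers.
#' @param conditionCol name of the column holding the condition labels.
#' @param contrast character(2): c(reference, test) level names.
#' @param dialect "tsv", "csv" or "auto".
#' @return data.frame with columns \code{sample}, \code{condition}, plus any
#'   extra covariates.
#' @export
readSampleSheet <- function(path, conditionCol = "condition",
                            contrast = NULL, dialect = c("auto", "tsv", "csv")) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
    sep <- if (dialect == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    makeSampleSheet(df, conditionCol = conditionCol, contrast = contrast)
}

#' Build a sample sheet from a data.frame
#'
#' @param df data.frame; first column (or a \code{sample} column) holds
#'   sample identifiers.
#' @inheritParams readSampleSheet
#' @return see [readSampleSheet()].
#' @export
makeSampleSheet <- function(df, conditionCol = "condition", contrast = NULL) {
    df <- as.data.frame(df)
    sampleCol <- if ("sample" %in% colnames(df)) "sample" else colnames(df)[1L]
    if (!conditionCol %in% colnames(df))
        stop("condition column '", conditionCol, "' not found")
    samples <- as.character(df[[sampleCol]])
    if (anyDuplicated(samples))
        stop("duplicated sample identifier(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    cond <- as.character(df[[conditionCol]])
    if (is.null(contrast)) {
        contrast <- unique(cond)
        if (length(contrast) != 2L)
            stop("condition has ", length(contrast),
                 " levels; supply a two-level contrast")
    }
    missing <- setdiff(contrast, cond)
    if (length(missing))
        stop("contrast level(s) absent from metadata: ",
             paste(missing, collapse = ", "))
    keep <- cond %in% contrast
    out <- data.frame(sample = samples[keep],
                      condition = factor(cond[keep], levels = contrast),
                      stringsAsFactors = FALSE)
    extras <- setdiff(colnames(df), c(sampleCol, conditionCol))
    for (nm in extras) out[[nm]] <- df[[nm]][keep]
    small <- table(out$condition) < 2L
    if (any(small))
        stop("condition level(s) with fewer than 2 samples: ",
             paste(names(small)[small], collapse = ", "),
             " (engines require replication)")
    out
}

#' Align a count matrix to a sample sheet
#'
#' Reorders count columns to the sheet's sample order. Count columns absent
#' from the sheet are dropped with a warning; sheet samples absent from the
#' counts are an error.
#'
#' @param counts matrix with sample column names.
#' @param sheet data.frame from [readSampleSheet()]/[makeSampleSheet()].
#' @return the reordered count matrix.
#' @export
alignSamples <- function(counts, sheet) {
    want <- sheet$sample
    have <- colnames(counts)
    if (!length(intersect(want, have)))
        stop("no overlap between count matrix samples and sample sheet")
    missing <- setdiff(want, have)
    if (length(missing))
        stop("sample(s) in metadata but not in counts: ",
             paste(missing, collapse = ", "))
    extra <- setdiff(have, want)
    if (length(extra))
        warning("dropping count column(s) not in sample sheet: ",
                paste(extra, collapse = ", "))
    counts[, want, drop = FALSE]
}

#' Assemble a DEExperiment from counts and metadata
#'
#' Convenience wrapper: [alignSamples()] then [DEExperiment()].
#'
#' @inheritParams alignSamples
#' @return a \linkS4class{DEExperiment}.
#' @export
buildExperiment <- function(counts, sheet) {
    m <- alignSamples(counts, sheet)
    extras <- sheet[, setdiff(colnames(sheet), c("sample", "condition")),
                    drop = FALSE]
    DEExperiment(m, sheet$condition,
                 extra = if (ncol(extras)) extras else NULL)
}
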