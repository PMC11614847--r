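#' Ordination plots (MDS / PCA)
#'
#' MDS: classical scaling of Euclidean distances over the 500 most variable
#' log2-CPM genes. PCA: first two components of the centered log2-CPM
#' matrix. Samples are colored by condition and the coordinates are also
#' written as TSV next to the plot.
#'
#' @param logcpm genes x samples log2-CPM matrix.
#' @param condition factor over samples.
#' @param kind "mds" or "pca".
#' @param path output PNG path.
#' @return data.frame of coordinates, invisibly; NULL (with a warning) if
#'   fewer than 3 samples.
#' @export
plotOrdination <- function(logcpm, condition, kind = c("mds", "pca"), path) {
    kind <- match.arg(kind)
    if (ncol(logcpm) < 3L) {
        warning("fewer than 3 samples; ", kind, " plot skipped")
        return(invisible(NULL))
    }
    if (kind == "mds") {
        v <- .rowVars(logcpm)
        top <- order(-v)[seq_len(min(500L, nrow(logcpm)))]
        xy <- stats::cmdscale(stats::dist(t(logcpm[top, , drop = FALSE])),
                              k = 2)
        labs <- c("MDS1", "MDS2")
    } else {
        pc <- stats::prcomp(t(logcpm), center = TRUE, scale. = FALSE)
        xy <- pc$x[, 1:2, drop = FALSE]
        labs <- c("PC1", "PC2")
    }
    coords <- data.frame(sample = colnames(logcpm), condition = condition,
                         axis1 = xy[, 1L], axis2 = xy[, 2L])
    utils::write.table(coords, sub("\\.png$", ".tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    grDevices::png(path, width = 600, height = 600)
    graphics::plot(xy, col = as.integer(condition), pch = 16,
                   xlab = labs[1L], ylab = labs[2L], main = toupper(kind))
    graphics::text(xy, labels = colnames(logcpm), pos = 3, cex = 0.7)
    graphics::legend("topright", legend = levels(condition),
                     col = seq_len(nlevels(condition)), pch = 16)
    grDevices::dev.off()
    invisible(coords)
}

#' Volcano plot
#'
#' log2FC versus -log10(padj) with the calling thresholds drawn.
#'
#' @param table data.frame with columns log2FC-like and padj-like; pass the
#'   column names via \code{lfcCol} / \code{padjCol}.
#' @param padjThr,lfcThr calling thresholds (drawn as lines).
#' @param path output PNG path.
#' @param lfcCol,padjCol column names.
#' @return the path, invisibly.
#' @export
plotVolcano <- function(table, padjThr = 0.05, lfcThr = 1, path,
                        lfcCol = "log2_fc", padjCol = "padj") {
    lfc <- table[[lfcCol]]
    padj <- table[[padjCol]]
    called <- callDE(padj, lfc, padjThr, lfcThr)
    grDevices::png(path, width = 700, height = 600)
    graphics::plot(lfc, -log10(pmax(padj, 1e-300)),
                   col = ifelse(called, "red", "grey40"), pch = 16,
                   cex = 0.5, xlab = "log2 fold change",
                   ylab = "-log10 adjusted p", main = "Volcano")
    graphics::abline(h = -log10(padjThr), lty = 2)
    graphics::abline(v = c(-lfcThr, lfcThr), lty = 2)
    grDevices::dev.off()
    invisible(path)
}

#' Heatmap of called DE genes
#'
#' Row-z-scored log2-CPM of the called genes, rows ordered by hierarchical
#' clustering (Euclidean distance, average linkage).
#'
#' @param logcpm genes x samples log2-CPM matrix.
#' @param deGenes character vector of called gene ids.
#' @param path output PNG path.
#' @return the path (NULL with a message when no genes are called).
#' @export
plotHeatmapDE <- function(logcpm, deGenes, path) {
    deGenes <- intersect(deGenes, rownames(logcpm))
    if (!length(deGenes)) {
        message("no DE genes; heatmap skipped")
        return(invisible(NULL))
    }
    m <- logcpm[deGenes, , drop = FALSE]
    sdv <- apply(m, 1L, stats::sd)
    z <- (m - rowMeans(m)) / ifelse(sdv > 0, sdv, 1)
    ord <- if (nrow(z) > 2)
        stats::hclust(stats::dist(z), method = "average")$order
    else seq_len(nrow(z))
    grDevices::png(path, width = 700, height = 700)
    graphics::image(t(z[rev(ord), , drop = FALSE]), axes = FALSE,
                    main = paste0("DE genes (n=", nrow(z), "), row z-score"),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(z)),
                   labels = colnames(z), las = 2, cex.axis = 0.7)
    grDevices::dev.off()
    invisible(path)
}

#' Before/after normalization box summary
#'
#' Per-sample five-number summaries of log2-CPM before and after applying
#' the normalization factors.
#'
#' @param counts raw counts matrix.
#' @param nf a \linkS4class{NormFactors}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plotNormalization <- function(counts, nf, path) {
    before <- cpm(counts, NULL, log = TRUE)
    after <- cpm(counts, nf, log = TRUE)
    grDevices::png(path, width = 900, height = 500)
    graphics::par(mfrow = c(1, 2))
    graphics::boxplot(before, las = 2, main = "log2-CPM (library size)",
                      cex.axis = 0.7, outline = FALSE)
    graphics::boxplot(after, las = 2,
                      main = paste0("log2-CPM (", nf@method, ")"),
                      cex.axis = 0.7, outline = FALSE)
    grDevices::dev.off()
    invisible(path)
}
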