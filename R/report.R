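#' Render the narrated run report
#'
#' Writes a self-contained markdown report listing every executed step in
#' order with a prose description, the per-approach DE call counts, the
#' truth-based metrics table for simulation runs, and links to the emitted
#' plots. The report is a view over the written TSVs: every number in it is
#' re-derivable from them.
#'
#' @param steps ordered list of step records (name, text) accumulated by
#'   [runPipeline()].
#' @param callCounts named integer vector of DE calls per approach.
#' @param metricsTab optional truth-metrics data.frame.
#' @param path output markdown path.
#' @return the path, invisibly.
#' @export
renderReport <- function(steps, callCounts = NULL, metricsTab = NULL,
                         path = "report.md") {
    lines <- c("# fuseDE run report", "",
               paste0("Generated by fuseDE ",
                      utils::packageVersion("fuseDE"), " on ",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "."), "",
               "## Executed steps", "")
    for (i in seq_along(steps))
        lines <- c(lines, sprintf("%d. **%s** — %s", i, steps[[i]]$name,
                                  steps[[i]]$text))
    if (!is.null(callCounts)) {
        lines <- c(lines, "", "## DE calls per approach", "",
                   "| approach | calls |", "|---|---|",
                   sprintf("| %s | %d |", names(callCounts), callCounts))
    }
    if (!is.null(metricsTab)) {
        lines <- c(lines, "", "## Truth-based metrics", "",
                   paste0("| ", paste(colnames(metricsTab),
                                      collapse = " | "), " |"),
                   paste0("|", paste(rep("---", ncol(metricsTab)),
                                     collapse = "|"), "|"))
        for (i in seq_len(nrow(metricsTab))) {
            vals <- vapply(metricsTab[i, ], function(v)
                if (is.numeric(v)) format(v, digits = 4) else
                    as.character(v), character(1L))
            lines <- c(lines, paste0("| ", paste(vals, collapse = " | "),
                                     " |"))
        }
    }
    lines <- c(lines, "", "## Plots", "",
               "- normalization.png — log2-CPM before/after normalization",
               "- mds.png / pca.png — sample ordination (coordinates in the matching .tsv)",
               "- volcano.png — mean log2FC vs Lancaster adjusted p",
               "- heatmap.png — row-z-scored log2-CPM of called DE genes")
    writeLines(lines, path)
    invisible(path)
}
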