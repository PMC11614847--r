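#' Run configuration
#'
#' Builds (and validates) the configuration consumed by [runPipeline()].
#' Defaults follow the standard workflow: rowsums filter at 10 total
#' counts, padj threshold 0.05, |log2FC| threshold 1, Lancaster combination
#' plus the Max-P intersection.
#'
#' @param filterMethod "rowsums", "by_expression" or "variance".
#' @param minTotal rowsums filter threshold.
#' @param padjThr adjusted-p calling threshold, in (0,1).
#' @param lfcThr absolute log2FC calling threshold, >= 0.
#' @param combiners combination methods to compute (Lancaster is always
#'   added; Max-P is always computed).
#' @param lancasterWeights positive Lancaster weights (default 2 each).
#' @param wilkinsonR Wilkinson order statistic, between 1 and 4.
#' @param withWilcoxon also run the Wilcoxon engine.
#' @param priorDf NB-exact tagwise shrinkage prior df.
#' @param nPerm score-test permutations (0 = asymptotic).
#' @param cooksFilter mask Wald p-values of Cook's-flagged genes.
#' @param seed integer seed.
#' @param filterArgs extra arguments for the chosen filter.
#' @return validated config list.
#' @export
runConfig <- function(filterMethod = "rowsums", minTotal = 10,
                      padjThr = 0.05, lfcThr = 1,
                      combiners = "lancaster", lancasterWeights = 2,
                      wilkinsonR = 1, withWilcoxon = FALSE, priorDf = 10,
                      nPerm = 0, cooksFilter = FALSE, seed = 1L,
                      filterArgs = list()) {
    stopifnot(padjThr > 0, padjThr < 1, lfcThr >= 0,
              wilkinsonR >= 1, wilkinsonR <= length(.ENGINES),
              all(lancasterWeights > 0))
    if (filterMethod == "rowsums" && !length(filterArgs))
        filterArgs <- list(minTotal = minTotal)
    list(filterMethod = filterMethod, filterArgs = filterArgs,
         padjThr = padjThr, lfcThr = lfcThr,
         combiners = union("lancaster", combiners),
         lancasterWeights = lancasterWeights, wilkinsonR = wilkinsonR,
         withWilcoxon = withWilcoxon, priorDf = priorDf, nPerm = nPerm,
         cooksFilter = cooksFilter, seed = as.integer(seed))
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [runConfig()] in snake_case (filter_method,
#' min_total, padj_threshold, lfc_threshold, combiners, lancaster_weights,
#' wilkinson_r, with_wilcoxon, prior_df, n_perm, cooks_filter, seed).
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
    runConfig(filterMethod = pick("filter_method", "rowsums"),
              minTotal = pick("min_total", 10),
              padjThr = pick("padj_threshold", 0.05),
              lfcThr = pick("lfc_threshold", 1),
              combiners = unlist(pick("combiners", "lancaster")),
              lancasterWeights = unlist(pick("lancaster_weights", 2)),
              wilkinsonR = pick("wilkinson_r", 1),
              withWilcoxon = pick("with_wilcoxon", FALSE),
              priorDf = pick("prior_df", 10),
              nPerm = pick("n_perm", 0),
              cooksFilter = pick("cooks_filter", FALSE),
              seed = pick("seed", 1L))
}

#' Run the full DE pipeline
#'
#' Single-command orchestration: read and validate inputs, filter, run the
#' four engines (plus Wilcoxon if requested), combine, and write every
#' table, plot, the JSON run summary and the narrated report into
#' \code{outdir}. On failure a \code{FAILED} marker file is left in the
#' output directory and the error is re-raised.
#'
#' @param counts count matrix, or path to a counts TSV/CSV.
#' @param metadata sample sheet data.frame, or path to a metadata file.
#' @param config list from [runConfig()] / [readRunConfig()].
#' @param outdir output directory (created).
#' @param conditionCol,contrast forwarded to [readSampleSheet()] when
#'   \code{metadata} is a path.
#' @param truth optional simulation truth data.frame; when given, the
#'   report includes truth-based metrics per approach.
#' @return (invisibly) a list with the experiment, engine tables, combined
#'   table and paths of everything written.
#' @export
runPipeline <- function(counts, metadata, config = runConfig(),
                        outdir = "fuseDE_run", conditionCol = "condition",
                        contrast = NULL, truth = NULL) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tryCatch(
        .runPipelineInner(counts, metadata, config, outdir, conditionCol,
                          contrast, truth),
        error = function(e) {
            writeLines(conditionMessage(e), file.path(outdir, "FAILED"))
            stop(e)
        })
}

.runPipelineInner <- function(counts, metadata, config, outdir,
                              conditionCol, contrast, truth) {
    set.seed(config$seed)
    steps <- list()
    note <- function(name, text, ...)
        steps[[length(steps) + 1L]] <<- list(name = name, text = text,
                                             data = list(...))
    if (is.character(counts)) counts <- readCounts(counts)
    if (is.character(metadata))
        metadata <- readSampleSheet(metadata, conditionCol, contrast)
    de0 <- buildExperiment(counts, metadata)
    note("input", sprintf(
        "Loaded %d genes x %d samples; contrast %s (test) vs %s (reference).",
        nrow(de0), ncol(de0), testLevel(de0), referenceLevel(de0)),
        genes = nrow(de0), samples = ncol(de0))

    de <- do.call(applyFilter,
                  c(list(de0, method = config$filterMethod),
                    config$filterArgs))
    note("filter", sprintf(
        "Low-expression filter '%s': %d of %d genes retained.",
        config$filterMethod, nrow(de), nrow(de0)),
        method = config$filterMethod, before = nrow(de0), after = nrow(de))

    nf <- tmmFactors(countsMatrix(de))
    sf <- medianOfRatios(countsMatrix(de))
    normTab <- data.frame(sample = colnames(de),
                          lib_size = colSums(countsMatrix(de)),
                          tmm_factor = normFactors(nf),
                          size_factor = normFactors(sf))
    utils::write.table(normTab, file.path(outdir, "norm_factors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plotNormalization(countsMatrix(de), nf,
                      file.path(outdir, "normalization.png"))
    note("normalize",
         "TMM factors (exact-NB / moderated-t / score engines) and median-of-ratios size factors (NB-Wald engine) computed; per-sample table in norm_factors.tsv.")

    engines <- runAllEngines(de, withWilcoxon = config$withWilcoxon,
                             priorDf = config$priorDf, nPerm = config$nPerm,
                             cooksFilter = config$cooksFilter,
                             seed = config$seed)
    writeEngineTables(engines, outdir)
    note("engines", sprintf(
        "Ran %d DE engines on %d genes: %s.", length(engines), nrow(de),
        paste(names(engines), collapse = ", ")))

    cooks <- attr(engines$nb_wald, "cooks")
    if (!is.null(cooks)) {
        fl <- which(cooks$flagged, arr.ind = TRUE)
        cooksTab <- data.frame(
            gene = rownames(countsMatrix(de))[fl[, 1L]],
            sample = colnames(de)[fl[, 2L]],
            cooks_distance = cooks$D[fl])
        utils::write.table(cooksTab, file.path(outdir, "cooks_flags.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("cooks", sprintf(
            "Cook's distance screening flagged %d gene/sample cells above the F(2, m-2) 99th percentile (%.2f); flags reported, not removed.",
            nrow(cooksTab), cooks$threshold), flagged = nrow(cooksTab))
    }

    combined <- suppressWarnings(combineAll(
        engines, combiners = config$combiners,
        lancasterWeights = config$lancasterWeights,
        wilkinsonR = config$wilkinsonR,
        padjThr = config$padjThr, lfcThr = config$lfcThr))
    utils::write.table(combined, file.path(outdir, "combined.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- approachCalls(engines, combined, config$padjThr, config$lfcThr)
    callCounts <- vapply(calls, sum, integer(1L))
    note("combine", sprintf(
        "Combined the four engines (%s; Max-P intersection always included). DE calls at padj <= %g and |log2FC| >= %g: %s.",
        paste(config$combiners, collapse = ", "), config$padjThr,
        config$lfcThr,
        paste(sprintf("%s=%d", names(callCounts), callCounts),
              collapse = ", ")))

    lc <- cpm(countsMatrix(de), nf, log = TRUE)
    plotOrdination(lc, conditions(de), "mds", file.path(outdir, "mds.png"))
    plotOrdination(lc, conditions(de), "pca", file.path(outdir, "pca.png"))
    plotVolcano(combined, config$padjThr, config$lfcThr,
                file.path(outdir, "volcano.png"),
                lfcCol = "mean_log2_fc", padjCol = "padj_lancaster")
    plotHeatmapDE(lc, combined$gene[combined$call_lancaster],
                  file.path(outdir, "heatmap.png"))
    note("plots",
         "Wrote MDS, PCA, volcano (Lancaster padj vs mean log2FC) and DE-gene heatmap.")

    metricsTab <- NULL
    if (!is.null(truth)) {
        truthDE <- truth$is_de[match(rownames(de), truth$gene)]
        metricsTab <- do.call(rbind, lapply(names(calls), function(ap) {
            met <- classificationMetrics(
                confusionCounts(calls[[ap]], truthDE))
            data.frame(approach = ap, as.data.frame(met))
        }))
        utils::write.table(metricsTab, file.path(outdir, "truth_metrics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("truth", "Scored every approach against the simulation truth (truth_metrics.tsv).")
    }

    summary <- list(
        package = "fuseDE",
        version = as.character(utils::packageVersion("fuseDE")),
        seed = config$seed,
        parameters = config[c("filterMethod", "padjThr", "lfcThr",
                              "combiners", "wilkinsonR", "priorDf",
                              "nPerm", "cooksFilter")],
        genes_input = nrow(de0), genes_filtered = nrow(de),
        samples = ncol(de), call_counts = as.list(callCounts),
        steps = vapply(steps, `[[`, character(1L), "name"))
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    renderReport(steps, callCounts, metricsTab,
                 file.path(outdir, "report.md"))
    invisible(list(experiment = de, engines = engines, combined = combined,
                   calls = calls, steps = steps, outdir = outdir,
                   metrics = metricsTab))
}
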