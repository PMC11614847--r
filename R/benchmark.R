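#' Confusion-matrix counts against simulation truth
#'
#' Tallies TP/FP/TN/FN for a vector of DE calls against the truth labels of
#' the same (post-filter) gene set. Direction is ignored: a call on a truly
#' DE gene is a TP regardless of sign, unless \code{directionAware = TRUE}
#' and a \code{callSign} is supplied, in which case a sign-discordant call
#' on a DE gene counts as FP.
#'
#' @param calls logical vector of DE calls.
#' @param truthDE logical vector, same length: gene truly DE.
#' @param directionAware require the call sign to match truth.
#' @param callSign,truthSign numeric sign vectors (used only when
#'   \code{directionAware}).
#' @return list with integer TP, FP, TN, FN.
#' @export
confusionCounts <- function(calls, truthDE, directionAware = FALSE,
                            callSign = NULL, truthSign = NULL) {
    if (length(calls) != length(truthDE))
        stop("calls and truth have different lengths")
    if (directionAware && !is.null(callSign) && !is.null(truthSign)) {
        tp <- sum(calls & truthDE & sign(callSign) == sign(truthSign))
        fp <- sum(calls) - tp
    } else {
        tp <- sum(calls & truthDE)
        fp <- sum(calls & !truthDE)
    }
    fn <- sum(!calls & truthDE)
    tn <- length(calls) - tp - fp - fn
    list(TP = as.integer(tp), FP = as.integer(fp),
         TN = as.integer(tn), FN = as.integer(fn))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, precision, F1 and Matthews correlation
#' coefficient; any 0/0 is 0 by convention.
#'
#' @param cc list with TP, FP, TN, FN (from [confusionCounts()]).
#' @return the input list extended with sensitivity, specificity,
#'   precision, F1, MCC.
#' @export
classificationMetrics <- function(cc) {
    safe <- function(num, den) if (den == 0) 0 else num / den
    tp <- cc$TP; fp <- cc$FP; tn <- cc$TN; fn <- cc$FN
    mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    c(cc, list(
        sensitivity = safe(tp, tp + fn),
        specificity = safe(tn, tn + fp),
        precision = safe(tp, tp + fp),
        F1 = safe(2 * tp, 2 * tp + fp + fn),
        MCC = if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen))
}

#' Extract per-approach DE calls from a run
#'
#' @param engines list from [runAllEngines()].
#' @param combined data.frame from [combineAll()].
#' @inheritParams callDE
#' @return named list of logical call vectors (engines, combiners, max_p).
#' @export
approachCalls <- function(engines, combined, padjThr = 0.05, lfcThr = 1) {
    out <- lapply(engines, function(t)
        callDE(t$padj, t$log2_fc, padjThr, lfcThr))
    for (m in sub("^call_", "",
                  grep("^call_", colnames(combined), value = TRUE)))
        out[[m]] <- combined[[paste0("call_", m)]]
    out$max_p <- combined$max_p
    out
}

#' Run the simulation benchmark grid
#'
#' For each (preset, replicate): simulate, filter (group-aware expression
#' filter, the benchmark's filtering mode), run all engines, combine, call
#' DE at the thresholds, and score every approach against truth. Returns a
#' long-format table with one row per approach x preset x replicate.
#'
#' @param presets vector of preset ids (1-9, "large").
#' @param nPerGroup samples per group.
#' @param nReplicates replicates per preset (default 10).
#' @param nGenes gene count per dataset (scaling preset DE counts
#'   proportionally); NULL = preset default.
#' @param seed base seed; streams are derived per (preset, replicate).
#' @param combiners combination methods to evaluate.
#' @param withWilcoxon include the Wilcoxon engine.
#' @inheritParams callDE
#' @return data.frame: approach, preset, n_per_group, replicate,
#'   TP/FP/TN/FN, sensitivity, specificity, precision, F1, MCC.
#' @export
runBenchmark <- function(presets = 1:9, nPerGroup = 3, nReplicates = 10,
                         nGenes = NULL, seed = 1L,
                         combiners = c("lancaster", "fisher", "stouffer",
                                       "wilkinson", "bonferroni_holm",
                                       "tippett"),
                         withWilcoxon = FALSE,
                         padjThr = 0.05, lfcThr = 1) {
    rows <- list()
    for (preset in presets) {
        cfg <- simPreset(preset, nPerGroup = nPerGroup, nGenes = nGenes)
        for (rep in seq_len(nReplicates)) {
            res <- tryCatch(
                .benchmarkOne(cfg, rep, seed, combiners, withWilcoxon,
                              padjThr, lfcThr),
                error = function(e)
                    stop("benchmark failed at preset ", preset,
                         ", replicate ", rep, ": ", conditionMessage(e),
                         call. = FALSE))
            for (ap in names(res)) {
                met <- classificationMetrics(res[[ap]])
                rows[[length(rows) + 1L]] <- data.frame(
                    approach = ap, preset = as.character(preset),
                    n_per_group = cfg$nPerGroup, replicate = rep,
                    TP = met$TP, FP = met$FP, TN = met$TN, FN = met$FN,
                    sensitivity = met$sensitivity,
                    specificity = met$specificity,
                    precision = met$precision, F1 = met$F1, MCC = met$MCC,
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

.benchmarkOne <- function(cfg, rep, seed, combiners, withWilcoxon,
                          padjThr, lfcThr) {
    sim <- simulateDataset(cfg, replicate = rep, seed = seed)
    de <- buildExperiment(sim$counts, sim$sheet)
    de <- filterByExpression(de)
    engines <- runAllEngines(de, withWilcoxon = withWilcoxon, seed = seed)
    combined <- suppressWarnings(
        combineAll(engines, combiners = combiners,
                   padjThr = padjThr, lfcThr = lfcThr))
    calls <- approachCalls(engines, combined, padjThr, lfcThr)
    truthDE <- sim$truth$is_de[match(rownames(de), sim$truth$gene)]
    lapply(calls, confusionCounts, truthDE = truthDE)
}

#' Aggregate benchmark results
#'
#' Mean and sd of each metric over replicates, per approach x preset.
#'
#' @param bench data.frame from [runBenchmark()].
#' @return aggregated data.frame.
#' @export
aggregateBenchmark <- function(bench) {
    metrics <- c("sensitivity", "specificity", "precision", "F1", "MCC")
    out <- NULL
    for (met in metrics) {
        ag <- stats::aggregate(bench[[met]],
                               by = bench[c("approach", "preset",
                                            "n_per_group")],
                               FUN = function(x) c(mean = mean(x),
                                                   sd = stats::sd(x)))
        d <- data.frame(ag[c("approach", "preset", "n_per_group")],
                        mean = ag$x[, "mean"], sd = ag$x[, "sd"])
        colnames(d)[4:5] <- paste0(met, c("_mean", "_sd"))
        out <- if (is.null(out)) d else merge(out, d)
    }
    out[order(out$preset, out$approach), ]
}

#' Line plots of benchmark sensitivity and specificity
#'
#' One panel per metric, approaches on the x axis, one line per preset.
#'
#' @param bench data.frame from [runBenchmark()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plotBenchmark <- function(bench, path) {
    ag <- aggregateBenchmark(bench)
    aps <- sort(unique(ag$approach))
    presets <- unique(ag$preset)
    grDevices::png(path, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
    for (met in c("sensitivity_mean", "specificity_mean")) {
        graphics::plot(NA, xlim = c(1, length(aps)), ylim = c(0, 1),
                       xaxt = "n", xlab = "", ylab = sub("_mean", "", met),
                       main = sub("_mean", "", met))
        graphics::axis(1, at = seq_along(aps), labels = aps, las = 2)
        for (i in seq_along(presets)) {
            d <- ag[ag$preset == presets[i], ]
            graphics::lines(match(d$approach, aps), d[[met]], col = i,
                            type = "b", pch = 16)
        }
        graphics::legend("bottomleft", legend = paste("preset", presets),
                         col = seq_along(presets), lty = 1, cex = 0.7)
    }
    invisible(path)
}
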