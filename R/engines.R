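#' Run all DE engines on one filtered experiment
#'
#' Runs the four core engines (NB exact, moderated t, NB Wald, score test)
#' and optionally the Wilcoxon alternative on the same filtered gene set.
#' TMM factors are computed once and shared by the engines that use them;
#' the Wald engine computes its own median-of-ratios size factors. Every
#' engine returns the identical gene set in identical order, with BH
#' adjusted p-values appended. Any engine failure aborts the run naming the
#' engine.
#'
#' @param de a filtered \linkS4class{DEExperiment}.
#' @param withWilcoxon also run the Wilcoxon rank-sum engine.
#' @param priorDf prior df for NB-exact tagwise dispersion shrinkage.
#' @param nPerm permutations for the score test (0 = asymptotic).
#' @param cooksFilter forwarded to [runNBWald()].
#' @param seed RNG seed (used only by sampled score-test permutations).
#' @return named list of DEResultTable data.frames, in the fixed engine
#'   order nb_exact, voom_limma, nb_wald, score_test (+ wilcoxon).
#' @export
runAllEngines <- function(de, withWilcoxon = FALSE, priorDf = 10,
                          nPerm = 0, cooksFilter = FALSE, seed = 1L) {
    nf <- tmmFactors(countsMatrix(de))
    runs <- list(
        nb_exact = function() runNBExact(de, nf, priorDf = priorDf),
        voom_limma = function() runVoomT(de, nf),
        nb_wald = function() runNBWald(de, cooksFilter = cooksFilter),
        score_test = function() runScoreTest(de, nf, nPerm = nPerm,
                                             seed = seed))
    if (withWilcoxon) runs$wilcoxon <- function() runWilcoxon(de, nf)
    out <- lapply(names(runs), function(id) {
        tryCatch(runs[[id]](), error = function(e)
            stop("engine '", id, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    })
    names(out) <- names(runs)
    out
}

#' Write one TSV per engine result
#'
#' @param tables named list from [runAllEngines()].
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
writeEngineTables <- function(tables, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(tables), function(id) {
        p <- file.path(dir, paste0("engine_", id, ".tsv"))
        utils::write.table(tables[[id]], p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        p
    }, character(1L))
    invisible(paths)
}
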