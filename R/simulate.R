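#' Synthetic-dataset presets
#'
#' The nine benchmark dataset types (plus the asymmetric "large" design):
#' negative-binomial counts over \code{nGenes} genes, a fixed number of
#' truly DE genes with an exact up/down split, and optional single or
#' random outlier injection.
#'
#' \tabular{lllll}{
#' preset \tab genes \tab DE genes \tab up fraction \tab outliers \cr
#' 1 \tab 12,500 \tab 0     \tab -    \tab none   \cr
#' 2 \tab 12,500 \tab 1,250 \tab 0.50 \tab none   \cr
#' 3 \tab 12,500 \tab 1,250 \tab 1.00 \tab none   \cr
#' 4 \tab 12,500 \tab 4,000 \tab 0.50 \tab none   \cr
#' 5 \tab 12,500 \tab 4,000 \tab 1.00 \tab none   \cr
#' 6 \tab 12,500 \tab 0     \tab -    \tab single \cr
#' 7 \tab 12,500 \tab 1,250 \tab 0.50 \tab single \cr
#' 8 \tab 12,500 \tab 0     \tab -    \tab random \cr
#' 9 \tab 12,500 \tab 1,250 \tab 0.50 \tab random \cr
#' large \tab 20,000 \tab 2,000 \tab 0.40 \tab none \cr
#' }
#'
#' @param preset integer 1-9 or "large".
#' @param nPerGroup samples per condition (3, 10 or 100 in the benchmark
#'   design; default 3, forced to 100 for "large").
#' @param nGenes override the gene count; the DE count and outlier counts
#'   scale proportionally (for reduced-size runs).
#' @return a list of simulation settings consumed by [simulateDataset()].
#' @export
simPreset <- function(preset, nPerGroup = 3, nGenes = NULL) {
    tab <- list(
        `1` = list(nDE = 0,    fracUp = 0,   outlier = "none"),
        `2` = list(nDE = 1250, fracUp = 0.5, outlier = "none"),
        `3` = list(nDE = 1250, fracUp = 1.0, outlier = "none"),
        `4` = list(nDE = 4000, fracUp = 0.5, outlier = "none"),
        `5` = list(nDE = 4000, fracUp = 1.0, outlier = "none"),
        `6` = list(nDE = 0,    fracUp = 0,   outlier = "single"),
        `7` = list(nDE = 1250, fracUp = 0.5, outlier = "single"),
        `8` = list(nDE = 0,    fracUp = 0,   outlier = "random"),
        `9` = list(nDE = 1250, fracUp = 0.5, outlier = "random"),
        large = list(nDE = 2000, fracUp = 0.4, outlier = "none"))
    key <- as.character(preset)
    if (!key %in% names(tab)) stop("unknown preset: ", preset)
    base <- tab[[key]]
    baseGenes <- if (key == "large") 20000L else 12500L
    if (key == "large") nPerGroup <- 100L
    if (is.null(nGenes)) nGenes <- baseGenes
    scale <- nGenes / baseGenes
    list(preset = key,
         nGenes = as.integer(nGenes),
         nDE = as.integer(round(base$nDE * scale)),
         fracUp = base$fracUp,
         outlier = base$outlier,
         nPerGroup = as.integer(nPerGroup))
}

#' Sample per-gene base expression and dispersion
#'
#' Parametric base-expression pool reproducing the canonical
#' mean-dispersion decay of bulk RNA-seq: \code{log2(mu) ~ Normal(6, 2.5)}
#' truncated to \code{mu >= 1}, and
#' \code{phi = (0.05 + 2.5 / mu) * LogNormal(0, 0.3)}.
#'
#' @param nGenes number of genes.
#' @return data.frame with columns \code{mu}, \code{phi}.
#' @export
sampleBaseExpression <- function(nGenes) {
    l2mu <- stats::rnorm(nGenes, mean = 6, sd = 2.5)
    redo <- which(l2mu < 0)
    while (length(redo)) {           # truncation by resampling
        l2mu[redo] <- stats::rnorm(length(redo), 6, 2.5)
        redo <- redo[l2mu[redo] < 0]
    }
    mu <- 2^l2mu
    phi <- (0.05 + 2.5 / mu) * stats::rlnorm(nGenes, 0, 0.3)
    data.frame(mu = mu, phi = phi)
}

#' Inject count outliers
#'
#' "single": 10\% of genes get exactly one sample's count multiplied by
#' Uniform(5, 10) (rounded). "random": every cell independently with
#' probability 5\%. Modified cells are recorded.
#'
#' @param counts genes x samples count matrix.
#' @param mode "single" or "random".
#' @param geneFrac fraction of genes hit in "single" mode (default 0.10).
#' @param cellProb per-cell probability in "random" mode (default 0.05).
#' @return list: \code{counts} (modified), \code{cells} data.frame
#'   (gene, sample, factor).
#' @export
injectOutliers <- function(counts, mode = c("single", "random"),
                           geneFrac = 0.10, cellProb = 0.05) {
    mode <- match.arg(mode)
    nG <- nrow(counts); nS <- ncol(counts)
    if (mode == "single") {
        hit <- sort(sample.int(nG, round(geneFrac * nG)))
        smp <- sample.int(nS, length(hit), replace = TRUE)
        fac <- stats::runif(length(hit), 5, 10)
        ij <- cbind(hit, smp)
    } else {
        sel <- which(stats::runif(nG * nS) < cellProb)
        ij <- cbind((sel - 1L) %% nG + 1L, (sel - 1L) %/% nG + 1L)
        fac <- stats::runif(nrow(ij), 5, 10)
    }
    counts[ij] <- round(counts[ij] * fac)
    cells <- data.frame(gene = rownames(counts)[ij[, 1L]],
                        sample = colnames(counts)[ij[, 2L]],
                        factor = fac, stringsAsFactors = FALSE)
    list(counts = counts, cells = cells)
}

#' Simulate one benchmark dataset with truth labels
#'
#' Negative-binomial counts for a two-group design. Per gene, a base mean
#' and dispersion are drawn from [sampleBaseExpression()]; \code{nDE} genes
#' are picked uniformly without replacement and an exact
#' \code{round(fracUp * nDE)} of them are upregulated in the test class,
#' the rest downregulated. Effect sizes are \code{S = 1.5 + Exp(mean 1)}
#' multiplying (or dividing) the test-class mean. Per-sample sequencing
#' depth factors are Uniform(0.7, 1.4). Outliers are injected afterwards
#' according to the preset. The RNG stream is derived from (seed, preset,
#' replicate), so replicates are independent and every call is
#' reproducible.
#'
#' @param cfg list from [simPreset()].
#' @param replicate replicate number (default 1).
#' @param seed base RNG seed.
#' @return list: \code{counts} (matrix), \code{sheet} (data.frame with
#'   sample/condition; level "G2" is the test class), \code{truth}
#'   (data.frame: gene, is_de, direction, true_log2_fc, base_mean,
#'   dispersion), \code{outliers} (data.frame of modified cells).
#' @export
simulateDataset <- function(cfg, replicate = 1L, seed = 1L) {
    if (cfg$nDE > cfg$nGenes) stop("nDE exceeds nGenes")
    presetId <- if (cfg$preset == "large") 10L else as.integer(cfg$preset)
    set.seed(as.integer((as.numeric(seed) * 7919 + presetId * 104729 +
                         replicate * 7907) %% 2147483647))
    nG <- cfg$nGenes
    nS <- 2L * cfg$nPerGroup
    base <- sampleBaseExpression(nG)
    genes <- sprintf("g%05d", seq_len(nG))

    direction <- integer(nG)
    trueLfc <- numeric(nG)
    if (cfg$nDE > 0) {
        deIdx <- sample.int(nG, cfg$nDE)
        nUp <- round(cfg$fracUp * cfg$nDE)
        dirs <- c(rep(1L, nUp), rep(-1L, cfg$nDE - nUp))
        direction[deIdx] <- dirs
        S <- 1.5 + stats::rexp(cfg$nDE, rate = 1)
        trueLfc[deIdx] <- dirs * log2(S)
    }

    depth <- stats::runif(nS, 0.7, 1.4)
    grp <- rep(1:2, each = cfg$nPerGroup)
    fc <- 2^trueLfc                      # multiplies the test-class mean
    counts <- matrix(0, nG, nS,
                     dimnames = list(genes, sprintf("s%03d", seq_len(nS))))
    for (j in seq_len(nS)) {
        mu <- base$mu * depth[j] * if (grp[j] == 2L) fc else 1
        counts[, j] <- stats::rnbinom(nG, size = 1 / base$phi, mu = mu)
    }
    outliers <- data.frame(gene = character(), sample = character(),
                           factor = numeric(), stringsAsFactors = FALSE)
    if (cfg$outlier != "none") {
        oi <- injectOutliers(counts, cfg$outlier)
        counts <- oi$counts
        outliers <- oi$cells
    }
    truth <- data.frame(gene = genes,
                        is_de = direction != 0L,
                        direction = direction,
                        true_log2_fc = trueLfc,
                        base_mean = base$mu,
                        dispersion = base$phi,
                        stringsAsFactors = FALSE)
    sheet <- data.frame(sample = colnames(counts),
                        condition = factor(c("G1", "G2")[grp],
                                           levels = c("G1", "G2")),
                        stringsAsFactors = FALSE)
    list(counts = counts, sheet = sheet, truth = truth,
         outliers = outliers, depth = stats::setNames(depth,
                                                      colnames(counts)))
}

#' Write a simulated dataset as the pipeline's input files
#'
#' Emits the counts TSV, metadata TSV and truth TSV that [runPipeline()]
#' (and external tools) can read back.
#'
#' @param sim list from [simulateDataset()].
#' @param dir output directory.
#' @return named character vector of paths, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(counts = file.path(dir, "counts.tsv"),
               metadata = file.path(dir, "metadata.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeCounts(sim$counts, paths["counts"])
    utils::write.table(sim$sheet, paths["metadata"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
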