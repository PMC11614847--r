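# Shared plumbing for the five DE engines. Every engine returns a
# DEResultTable: a data.frame with one row per (filtered) gene, columns
# gene / base_mean / log2_fc / stat / p_value / padj, attribute "engine".

.ENGINES <- c("nb_exact", "voom_limma", "nb_wald", "score_test")

.engineResult <- function(gene, baseMean, log2fc, stat, p, engine) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    out <- data.frame(gene = gene,
                      base_mean = as.numeric(baseMean),
                      log2_fc = as.numeric(log2fc),
                      stat = as.numeric(stat),
                      p_value = as.numeric(p),
                      padj = bhAdjust(p),
                      stringsAsFactors = FALSE)
    attr(out, "engine") <- engine
    out
}

.groupIndex <- function(de) {
    grp <- as.integer(conditions(de))  # 1 = reference, 2 = test
    list(g1 = which(grp == 1L), g2 = which(grp == 2L), grp = grp)
}

# log2 ratio of group means with a pseudo-count keeping output finite
.log2fcOfMeans <- function(m, g1, g2, prior = 0.125) {
    log2((rowMeans(m[, g2, drop = FALSE]) + prior) /
         (rowMeans(m[, g1, drop = FALSE]) + prior))
}
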