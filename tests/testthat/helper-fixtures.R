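# Shared fixtures, all generated in code.

# small deterministic count matrix
fixtureCounts <- function(nGenes = 10, nSamples = 6, seed = 42,
                          lambda = 50) {
    set.seed(seed)
    m <- matrix(rpois(nGenes * nSamples, lambda), nrow = nGenes,
                dimnames = list(paste0("g", seq_len(nGenes)),
                                paste0("s", seq_len(nSamples))))
    storage.mode(m) <- "double"
    m
}

fixtureSheet <- function(nPerGroup = 3, levels = c("A", "B")) {
    n <- 2 * nPerGroup
    data.frame(sample = paste0("s", seq_len(n)),
               condition = factor(rep(levels, each = nPerGroup),
                                  levels = levels),
               stringsAsFactors = FALSE)
}

fixtureExperiment <- function(nGenes = 10, nPerGroup = 3, seed = 42,
                              lambda = 50) {
    m <- fixtureCounts(nGenes, 2 * nPerGroup, seed, lambda)
    buildExperiment(m, fixtureSheet(nPerGroup))
}

# NB counts with both groups drawn from one law (null fixture)
nullNBExperiment <- function(nGenes = 500, nPerGroup = 5, mu = 100,
                             phi = 0.1, seed = 7) {
    set.seed(seed)
    n <- 2 * nPerGroup
    m <- matrix(rnbinom(nGenes * n, size = 1 / phi, mu = mu), nrow = nGenes,
                dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                                paste0("s", seq_len(n))))
    storage.mode(m) <- "double"
    buildExperiment(m, fixtureSheet(nPerGroup))
}
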