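# Combiner oracles are computed inline from the defining distributions
# (chi-square, normal, Beta, order statistics), independent of the package.

test_that("combiners match their distributional oracles", {
    # Fisher
    expect_equal(fisherCombine(c(1, 1, 1, 1)), 1)
    expect_equal(fisherCombine(c(0.5, 0.5)),
                 pchisq(-2 * (log(0.5) + log(0.5)), 4, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(fisherCombine(c(0.5, 0.5)), 0.59657, tolerance = 1e-4)
    # Stouffer
    expect_equal(stoufferCombine(rep(0.5, 4)), 0.5, tolerance = 1e-12)
    zOracle <- (qnorm(0.95) * 2) / sqrt(2)
    expect_equal(stoufferCombine(c(0.05, 0.05)),
                 pnorm(zOracle, lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(stoufferCombine(c(0.05, 0.05)), 0.01000, tolerance = 1e-3)
    # Lancaster, weights 4: T = 2 * qchisq(0.5, 4) vs chi-square(8)
    TOracle <- 2 * qchisq(0.5, 4)
    expect_equal(lancasterCombine(c(0.5, 0.5), w = c(4, 4)),
                 pchisq(TOracle, 8, lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(lancasterCombine(c(0.5, 0.5), w = c(4, 4)), 0.56785,
                 tolerance = 1e-4)
    expect_equal(lancasterCombine(rep(1, 4)), 1, tolerance = 1e-12)
    expect_error(lancasterCombine(c(0.5, 0.5), w = c(1, -1)), "positive")
    # Wilkinson r = k: Beta(4,1) cdf is x^4
    expect_equal(wilkinsonCombine(rep(0.5, 4), r = 4), 0.5^4,
                 tolerance = 1e-12)
    expect_equal(wilkinsonCombine(rep(1, 4), r = 2), 1)
    expect_error(wilkinsonCombine(rep(0.5, 4), r = 5), "1..k")
    # Holm
    expect_equal(bonferroniHolmCombine(c(0.01, 0.5, 0.5, 0.5)), 0.04)
    expect_equal(bonferroniHolmCombine(rep(1, 4)), 1)
    expect_equal(bonferroniHolmCombine(0.2), 0.2)
    # Tippett
    expect_equal(tippettCombine(c(0.01, 0.5, 0.5, 0.5)), 1 - 0.99^4)
    expect_equal(tippettCombine(c(0, 0.5)), 0, tolerance = 1e-15)
    expect_equal(tippettCombine(rep(1, 4)), 1, tolerance = 1e-12)
})

test_that("combiner identities hold: Lancaster(2)=Fisher, Wilkinson(1)=Tippett", {
    set.seed(17)
    for (i in 1:50) {
        p <- runif(4)
        expect_lt(abs(lancasterCombine(p, w = 2) - fisherCombine(p)), 1e-10)
        expect_identical(wilkinsonCombine(p, r = 1), tippettCombine(p))
    }
})

test_that("combiners are symmetric, monotone maps into [0,1]", {
    set.seed(23)
    fns <- list(fisher = fisherCombine, stouffer = stoufferCombine,
                lancaster = lancasterCombine,
                wilkinson = function(p) wilkinsonCombine(p, 2),
                holm = bonferroniHolmCombine, tippett = tippettCombine)
    for (i in 1:25) {
        p <- runif(4)
        for (nm in names(fns)) {
            f <- fns[[nm]]
            v <- f(p)
            expect_true(v >= 0 && v <= 1, label = nm)
            expect_equal(f(sample(p)), v, tolerance = 1e-12, label = nm)
            # raising one input can only raise the output
            j <- sample(4, 1)
            p2 <- p; p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
            expect_gte(f(p2) + 1e-12, v)
        }
    }
    # any input driven to 0 drives Fisher to 0
    expect_lt(fisherCombine(c(1e-300, 0.9, 0.9, 0.9)), 1e-290)
})

test_that("combined p-values of uniform inputs are uniform", {
    set.seed(29)
    P <- matrix(runif(10000 * 4), ncol = 4)
    for (m in c("fisher", "stouffer", "lancaster", "wilkinson", "tippett",
                "bonferroni_holm")) {
        pc <- fuseDE:::.combineMatrix(P, m, w = if (m == "lancaster") 2
                                              else 1, r = 1)
        if (m == "bonferroni_holm") {
            # Holm is valid but conservative, not exactly uniform
            expect_lte(mean(pc <= 0.05), 0.055)
        } else {
            expect_gt(ks.test(pc, "punif")$p.value, 0.01, label = m)
        }
        expect_true(all(pc >= 0 & pc <= 1))
    }
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    set.seed(5)
    p <- runif(200)^2
    padj <- bhAdjust(p)
    expect_true(all(padj >= p))
    expect_true(all(padj <= 1))
    # NA excluded from the effective test count
    pn <- c(0.01, NA, 0.02)
    expect_equal(bhAdjust(pn), c(0.02, NA, 0.02))
    expect_error(bhAdjust(c(0.5, 1.2)), "0,1")
})

test_that("DE calling uses inclusive bounds", {
    expect_true(callDE(0.05, 1, padjThr = 0.05, lfcThr = 1))
    expect_false(callDE(0.051, 5, padjThr = 0.05, lfcThr = 1))
    expect_true(callDE(0.01, -1.0, padjThr = 0.05, lfcThr = 1))
    expect_false(callDE(0.01, 0.99, padjThr = 0.05, lfcThr = 1))
    expect_true(callDE(0.01, 0, padjThr = 0.05, lfcThr = 0))
    expect_false(callDE(NA, 3))
})

test_that("Max-P intersection takes the least significant p of full agreement", {
    mk <- function(p, padj, lfc) data.frame(
        gene = paste0("g", seq_along(p)), base_mean = 10, log2_fc = lfc,
        stat = 0, p_value = p, padj = padj)
    tabs <- list(
        nb_exact = mk(c(0.01, 0.001), c(0.02, 0.002), c(2, 2)),
        voom_limma = mk(c(0.02, 0.001), c(0.03, 0.002), c(2, 2)),
        nb_wald = mk(c(0.03, 0.001), c(0.04, 0.002), c(2, 2)),
        score_test = mk(c(0.04, 0.2), c(0.05, 0.3), c(2, 2)))
    mp <- maxPIntersect(tabs)
    expect_identical(mp$gene, "g1")        # g2 fails in one engine
    expect_equal(mp$p_max, 0.04)
    # no overlap is an empty table, not an error
    tabs$score_test$padj <- c(0.9, 0.9)
    mp0 <- maxPIntersect(tabs)
    expect_identical(nrow(mp0), 0L)
})

test_that("mean log2FC averages on the log scale and counts discordance", {
    mk <- function(lfc) data.frame(gene = paste0("g", seq_along(lfc)),
                                   base_mean = 1, log2_fc = lfc, stat = 0,
                                   p_value = 0.5, padj = 0.5)
    tabs <- list(nb_exact = mk(c(1, 2, 1)), voom_limma = mk(c(1, 0, -1)),
                 nb_wald = mk(c(1, 0, 1)), score_test = mk(c(1, 0, -1)))
    mfc <- meanLog2FC(tabs)
    expect_equal(mfc$mean_log2_fc, c(1, 0.5, 0))
    expect_equal(mfc$discordance, c(0, 0, 2))
    # linear mode is the arithmetic mean of linear FC
    lin <- meanLog2FC(tabs, scale = "linear")
    expect_equal(lin$mean_log2_fc[1], 1)
    expect_equal(lin$mean_log2_fc[2], log2(mean(2^c(2, 0, 0, 0))))
})

test_that("combineAll produces coherent combined tables", {
    cfg <- simPreset(2, nPerGroup = 3, nGenes = 300)
    sim <- simulateDataset(cfg, 1, seed = 11)
    de <- filterByExpression(buildExperiment(sim$counts, sim$sheet))
    eng <- runAllEngines(de)
    comb <- combineAll(eng, combiners = c("lancaster", "fisher",
                                          "stouffer", "tippett"))
    expect_identical(comb$gene, rownames(de))
    expect_true(all(comb$padj_fisher >= comb$p_fisher, na.rm = TRUE))
    # lancaster default weights reduce to fisher
    expect_equal(comb$p_lancaster, comb$p_fisher, tolerance = 1e-10)
    # max_p members are exactly the genes called by all four engines
    allCalls <- Reduce(`&`, lapply(eng[1:4], function(t)
        callDE(t$padj, t$log2_fc)))
    expect_identical(comb$max_p, unname(allCalls))
    expect_true(all(is.na(comb$p_max[!comb$max_p])))
    # identical engine tables -> combined ranking equals single-engine ranking
    same <- list(nb_exact = eng$nb_exact, voom_limma = eng$nb_exact,
                 nb_wald = eng$nb_exact, score_test = eng$nb_exact)
    same <- lapply(same, function(t) { attr(t, "engine") <- NULL; t })
    cs <- combineAll(same, combiners = "fisher")
    expect_identical(order(cs$p_fisher), order(eng$nb_exact$p_value))
})
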