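# Engine contracts and statistical behavior. Oracles: closed forms
# (binomial conditional test, pooled t), enumeration, and null simulations.

test_that("NB exact test reduces to the binomial conditional test at phi=0", {
    oracle <- binom.test(5, 15, p = 0.5)$p.value
    expect_equal(fuseDE:::.nbExactPValue(5, 10, 1, 1, 0), oracle,
                 tolerance = 1e-12)
    # and with unequal group sizes the conditional proportion shifts
    oracle2 <- binom.test(5, 15, p = 1 / 3)$p.value
    expect_equal(fuseDE:::.nbExactPValue(5, 10, 1, 2, 0), oracle2,
                 tolerance = 1e-12)
    # pruned-range path agrees with the full-range computation
    full <- fuseDE:::.nbExactPValue(2600, 3000, 3, 3, 0.05)
    expect_gt(2600 + 3000, 5000)  # exercised the pruned branch
    mu <- 5600 / 6
    lp <- dnbinom(0:5600, size = 3 / 0.05, mu = 3 * mu, log = TRUE) +
        dnbinom(5600:0, size = 3 / 0.05, mu = 3 * mu, log = TRUE)
    expect_equal(full, fuseDE:::.minlikeP(lp, 2601), tolerance = 1e-9)
})

test_that("NB exact engine finds an obvious DE gene and stays finite", {
    m <- fixtureCounts(20, 6, seed = 8, lambda = 120)
    m[1, ] <- c(0, 0, 0, 50, 60, 55)
    de <- buildExperiment(m, fixtureSheet(3))
    res <- runNBExact(de)
    expect_lt(res$p_value[1], 1e-4)
    expect_gt(res$log2_fc[1], 4)
    expect_true(all(is.finite(res$log2_fc)))
    expect_true(all(is.finite(res$p_value)))
})

test_that("engine p-values are calibrated under the null", {
    de <- nullNBExperiment(nGenes = 2000, nPerGroup = 10, mu = 100,
                           phi = 0.1, seed = 7)
    eng <- runAllEngines(de, withWilcoxon = TRUE)
    for (id in c("nb_exact", "voom_limma", "nb_wald", "score_test",
                 "wilcoxon")) {
        frac <- mean(eng[[id]]$p_value <= 0.05)
        expect_gt(frac, 0.02)
        expect_lt(frac, 0.08)
    }
    # continuous-statistic engines: full-distribution uniformity (the
    # exact test has discrete ties, hence suppressed KS warnings)
    expect_gt(suppressWarnings(
        ks.test(eng$voom_limma$p_value, "punif"))$p.value, 0.01)
    expect_gt(suppressWarnings(
        ks.test(eng$nb_exact$p_value, "punif"))$p.value, 0.01)
})

test_that("weighted group fit with unit weights equals the pooled t", {
    set.seed(21)
    y <- matrix(rnorm(2 * 8, mean = 5), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
    idx <- list(g1 = 1:4, g2 = 5:8, grp = rep(1:2, each = 4))
    fit <- fuseDE:::.weightedGroupFit(y, NULL, idx)
    for (g in 1:2) {
        tt <- t.test(y[g, 5:8], y[g, 1:4], var.equal = TRUE)
        tMine <- fit$beta[g] /
            sqrt(fit$s2[g] * (1 / fit$W1[g] + 1 / fit$W2[g]))
        expect_equal(unname(tMine), unname(tt$statistic), tolerance = 1e-10)
        expect_equal(unname(fit$beta[g]),
                     unname(diff(rev(tt$estimate))), tolerance = 1e-10)
    }
})

test_that("variance moderation leaves homogeneous variances unchanged", {
    s2 <- rep(2.5, 20)
    mod <- fuseDE:::.moderateVariances(s2, d = 4)
    expect_equal(mod$s2post, s2)
    expect_true(is.infinite(mod$d0))
    # heterogeneous variances shrink toward the middle
    s2h <- c(rep(0.5, 50), rep(4, 50))
    modh <- fuseDE:::.moderateVariances(s2h, d = 4)
    expect_true(all(modh$s2post[1:50] > 0.5))
    expect_true(all(modh$s2post[51:100] < 4))
})

test_that("score test permutations enumerate distinct label swaps", {
    m <- fixtureCounts(10, 6, seed = 13, lambda = 100)
    m[1, ] <- c(10, 12, 11, 400, 380, 390)   # clearly DE
    de <- buildExperiment(m, fixtureSheet(3))
    res <- runScoreTest(de, nPerm = 1000)
    expect_identical(attr(res, "n_perm_used"), ncol(combn(6, 3)))  # 20
    # the centered score statistic is invariant under label complement, so
    # the observed labelling and its mirror both reach Q_obs: min p = 2/20
    expect_equal(res$p_value[1], 2 / 20)
    # constant gene convention (identical columns -> constant log-CPM)
    m2 <- m[, c(1, 1, 1, 1, 1, 1)]
    colnames(m2) <- paste0("s", 1:6)
    res2 <- runScoreTest(buildExperiment(m2, fixtureSheet(3)))
    expect_true(all(res2$p_value == 1))
    expect_true(all(res2$log2_fc == 0))
})

test_that("Wilcoxon engine matches the exact rank-sum distribution", {
    # many identical background genes keep TMM factors at 1 and libraries
    # equal, so CPM preserves the crafted orderings
    m <- matrix(100, nrow = 20, ncol = 6,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
    m[1, ] <- c(1, 2, 3, 4, 5, 6)
    m[2, ] <- 7
    m[20, ] <- 127 - m[1, ]            # equalize libraries
    de <- buildExperiment(m, fixtureSheet(3))
    res <- runWilcoxon(de)
    expect_equal(res$p_value[1], 0.1)        # extreme split of 3v3, exact
    expect_equal(res$p_value[2], 1)          # all tied
    # monotone transform invariance: squaring the counts can't change ranks
    m4 <- m; m4[1, ] <- c(1, 4, 9, 16, 25, 36)
    m4[20, ] <- 200 - m4[1, ]
    de4 <- buildExperiment(m4, fixtureSheet(3))
    expect_equal(runWilcoxon(de4)$p_value[1], 0.1)
})

test_that("label swap flips log2FC and preserves p for every engine", {
    set.seed(31)
    cfg <- simPreset(2, nPerGroup = 3, nGenes = 120)
    sim <- simulateDataset(cfg, 1, seed = 5)
    sheetSwap <- sim$sheet
    sheetSwap$condition <- factor(sim$sheet$condition,
                                  levels = c("G2", "G1"))
    de <- buildExperiment(sim$counts, sim$sheet)
    deS <- buildExperiment(sim$counts, sheetSwap)
    a <- runAllEngines(de, withWilcoxon = TRUE)
    b <- runAllEngines(deS, withWilcoxon = TRUE)
    for (id in names(a)) {
        expect_equal(b[[id]]$log2_fc, -a[[id]]$log2_fc, tolerance = 1e-6,
                     label = id)
        expect_equal(b[[id]]$p_value, a[[id]]$p_value, tolerance = 1e-6,
                     label = id)
    }
})

test_that("engines are invariant to gene order", {
    cfg <- simPreset(2, nPerGroup = 3, nGenes = 80)
    sim <- simulateDataset(cfg, 1, seed = 9)
    de <- buildExperiment(sim$counts, sim$sheet)
    set.seed(1); perm <- sample(nrow(sim$counts))
    deP <- buildExperiment(sim$counts[perm, ], sim$sheet)
    a <- runNBExact(de); b <- runNBExact(deP)
    expect_equal(b$p_value[match(a$gene, b$gene)], a$p_value)
    av <- runVoomT(de); bv <- runVoomT(deP)
    expect_equal(bv$p_value[match(av$gene, bv$gene)], av$p_value)
})

test_that("NB Wald keeps far-above-trend dispersions unshrunk", {
    set.seed(41)
    n <- 400
    mu <- round(2^runif(n, 4, 9))
    phi <- rep(0.05, n)
    phi[1] <- 3                       # a wild gene, way above the trend
    m <- matrix(rnbinom(n * 10, size = rep(1 / phi, 10),
                        mu = rep(mu, 10)), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:10)))
    de <- buildExperiment(m + 1, fixtureSheet(5))
    res <- runNBWald(de)
    mle <- attr(res, "dispGeneEst")
    map <- attr(res, "dispersion")
    trend <- attr(res, "trendCoef")
    above <- log2(mle / (trend["a0"] + trend["a1"] / res$base_mean)) > 2
    expect_true(above[1])
    expect_equal(map[above], mle[above], ignore_attr = TRUE)
    # shrunk genes move toward the trend
    expect_lt(sd(log(map[!above])), sd(log(mle[!above])))
})

test_that("runAllEngines enforces the shared contract", {
    cfg <- simPreset(2, nPerGroup = 3, nGenes = 500)
    sim <- simulateDataset(cfg, 1, seed = 3)
    de <- filterByExpression(buildExperiment(sim$counts, sim$sheet))
    eng <- runAllEngines(de, withWilcoxon = TRUE)
    expect_named(eng, c("nb_exact", "voom_limma", "nb_wald", "score_test",
                        "wilcoxon"))
    for (t in eng) {
        expect_identical(t$gene, rownames(de))
        expect_true(all(t$padj >= t$p_value - 1e-12, na.rm = TRUE))
        expect_true(all(t$p_value >= 0 & t$p_value <= 1, na.rm = TRUE))
    }
    # determinism: a second run is identical
    eng2 <- runAllEngines(de, withWilcoxon = TRUE)
    expect_identical(eng, eng2)
    # a strongly DE spike-in gets a concordant sign everywhere
    strong <- sim$truth$gene[which.max(abs(sim$truth$true_log2_fc) *
                                       sim$truth$is_de *
                                       (sim$truth$base_mean > 50))]
    if (strong %in% rownames(de)) {
        sgn <- sign(sim$truth$true_log2_fc[sim$truth$gene == strong])
        for (t in eng[1:4])
            expect_equal(sign(t$log2_fc[t$gene == strong]), sgn,
                         label = attr(t, "engine"))
    }
})
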