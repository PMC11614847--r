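test_that("rowsums filter keeps exactly the genes at the threshold", {
    m <- matrix(c(3, 3, 3, 4, 3, 3, 4, 4, 3), nrow = 3, byrow = TRUE)
    m <- cbind(m, m)  # totals 18, 20, 22 over 6 samples
    dimnames(m) <- list(c("a", "b", "c"), paste0("s", 1:6))
    de <- buildExperiment(m, fixtureSheet(3))
    expect_identical(rownames(filterRowSums(de, 20)), c("b", "c"))
    expect_identical(rownames(filterRowSums(de, 0)), rownames(de))
    zero <- buildExperiment(matrix(0, 2, 6,
        dimnames = list(c("a", "b"), paste0("s", 1:6))) , fixtureSheet(3))
    expect_error(filterRowSums(zero, 1), "lower")
    # idempotence and subset property
    f <- filterRowSums(de, 20)
    expect_identical(rownames(filterRowSums(f, 20)), rownames(f))
    expect_true(all(rownames(f) %in% rownames(de)))
})

test_that("expression filter matches the group-aware rule and its oracle", {
    skip_if_not_installed("edgeR")
    set.seed(11)
    m <- matrix(rnbinom(300 * 6, size = 2, mu = rep(round(runif(300, 0, 80)),
                                                    6)),
                nrow = 300, dimnames = list(sprintf("g%03d", 1:300),
                                            paste0("s", 1:6)))
    de <- buildExperiment(m, fixtureSheet(3))
    mine <- rownames(m) %in% rownames(filterByExpression(de))
    ref <- unname(edgeR::filterByExpr(m, group = rep(c("A", "B"), each = 3)))
    expect_identical(mine, ref)

    # hand-evaluated corner: CPM above cutoff in exactly 3 samples, total
    # above min_total -> kept
    lib <- 1e5
    base <- matrix(lib / 10, nrow = 4, ncol = 6,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    base[2, ] <- c(40, 40, 40, 0, 0, 0)   # CPM 400 >= cutoff 100 in 3 samples
    base[3, ] <- 0                        # zero everywhere -> removed
    base[4, ] <- c(1, 1, 1, 1, 1, 0)      # CPM 10 < cutoff -> removed
    de2 <- buildExperiment(round(base), fixtureSheet(3))
    kept <- rownames(filterByExpression(de2))
    expect_true("g2" %in% kept)
    expect_false(any(c("g3", "g4") %in% kept))
    expect_true("g1" %in% kept)
})

test_that("variance filter ranks by log2-CPM variance", {
    # equal libraries so the constant-count gene has log2-CPM variance 0
    m <- matrix(0, nrow = 3, ncol = 6,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
    m[1, ] <- 50                        # constant -> variance 0
    m[2, ] <- c(10, 400, 10, 400, 10, 400)
    m[3, ] <- 500 - m[2, ]
    de <- buildExperiment(m, fixtureSheet(3))
    v <- apply(cpm(m, log = TRUE), 1, var)
    expect_identical(rownames(filterByVariance(de, topN = 1)),
                     names(which.max(v)))
    expect_false("g1" %in%
        rownames(filterByVariance(de, minVariance = 1e-6)))
    expect_identical(rownames(filterByVariance(de, topN = 3)), rownames(de))
    expect_warning(filterByVariance(de, topN = 10), "keeping all")
    expect_error(filterByVariance(de), "exactly one")
    expect_error(filterByVariance(de, minVariance = 1, topN = 1),
                 "exactly one")
})

test_that("TMM factors match the reference implementation", {
    skip_if_not_installed("edgeR")
    set.seed(3)
    m <- matrix(rnbinom(400 * 8, size = 5,
                        mu = rep(round(runif(400, 5, 500)), 8)),
                nrow = 400, dimnames = list(sprintf("g%03d", 1:400),
                                            paste0("s", 1:8)))
    mine <- normFactors(tmmFactors(m))
    ref <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("TMM factors behave under symmetry and pure depth change", {
    m <- fixtureCounts(10, 4, seed = 2, lambda = 200)
    same <- m[, c(1, 1, 1, 1)]
    colnames(same) <- paste0("s", 1:4)
    expect_equal(unname(normFactors(tmmFactors(same))), rep(1, 4))
    # doubling a column is pure depth: both factors 1
    two <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
    expect_equal(unname(normFactors(tmmFactors(two))), c(1, 1))
    # permutation equivariance
    f <- normFactors(tmmFactors(m))
    perm <- c(3, 1, 4, 2)
    fp <- normFactors(tmmFactors(m[, perm]))
    expect_equal(unname(fp), unname(f[perm]))
    # gene-order invariance
    fg <- normFactors(tmmFactors(m[sample(nrow(m)), ]))
    expect_equal(fg, f)
    # geometric mean 1
    expect_lt(abs(mean(log(f))), 1e-12)
})

test_that("median-of-ratios matches its closed form and oracle", {
    skip_if_not_installed("DESeq2")
    m <- fixtureCounts(12, 2, seed = 9, lambda = 100) + 1
    two <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
    sf <- normFactors(medianOfRatios(two))
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    set.seed(4)
    big <- matrix(rnbinom(300 * 6, size = 5,
                          mu = rep(round(runif(300, 10, 400)), 6)) + 1,
                  nrow = 300, dimnames = list(sprintf("g%03d", 1:300),
                                              paste0("s", 1:6)))
    expect_equal(unname(normFactors(medianOfRatios(big))),
                 unname(DESeq2::estimateSizeFactorsForMatrix(big)),
                 tolerance = 1e-10)
    # identical columns -> all 1; single sample -> 1
    same <- big[, c(1, 1, 1)]; colnames(same) <- paste0("s", 1:3)
    expect_equal(unname(normFactors(medianOfRatios(same))), rep(1, 3))
    one <- big[, 1, drop = FALSE]
    expect_equal(unname(normFactors(medianOfRatios(one))), 1)
    # no all-positive gene -> error pointing at TMM
    z <- big; z[cbind(seq_len(nrow(z)), rep_len(1:6, nrow(z)))] <- 0
    expect_error(medianOfRatios(z), "TMM")
})

test_that("CPM arithmetic is exact and depth-invariant", {
    m <- matrix(c(100, rep(1, 5)), nrow = 1,
                dimnames = list("g1", paste0("s", 1:6)))
    m2 <- rbind(m, other = 1e6 - colSums(m))
    expect_equal(cpm(m2)["g1", "s1"], 100)
    # doubling a sample leaves its CPM unchanged
    d <- fixtureCounts(5, 4)
    expect_equal(cpm(cbind(d, dbl = 2 * d[, 1]))[, "dbl"],
                 cpm(d)[, 1], ignore_attr = TRUE)
    # log-CPM of a zero count, prior 0.5, library 1e6
    z <- matrix(c(0, 1e6), nrow = 2, dimnames = list(c("g0", "g1"), "s1"))
    expect_equal(cpm(z, log = TRUE)["g0", 1],
                 log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
})

test_that("Cook's distance screening flags influential cells", {
    de <- fixtureExperiment(nGenes = 30, nPerGroup = 3, lambda = 100)
    m <- countsMatrix(de)
    # perfect fit -> D = 0
    phi <- rep(0.1, nrow(m))
    cd0 <- cooksDistance(m, m, phi, conditions(de))
    expect_equal(max(cd0$D), 0)
    # balanced 3v3 design: hat values 1/3 when weights are equal in group
    mu <- matrix(rowMeans(m), nrow(m), ncol(m))
    cdb <- cooksDistance(m, mu, phi, conditions(de))
    w <- mu / (1 + phi * mu)
    h <- w[1, 1] / sum(w[1, 1:3])
    expect_equal(h, 1 / 3)
    # inflating one count raises that cell's D
    m2 <- m; m2[1, 1] <- m2[1, 1] * 10
    cd2 <- cooksDistance(m2, mu, phi, conditions(de))
    expect_gt(cd2$D[1, 1], cdb$D[1, 1])
    # no residual df -> skipped with warning
    tiny <- m[, 1:2]
    expect_warning(
        out <- cooksDistance(tiny, mu[, 1:2], phi,
                             factor(c("A", "B"))), "skipped")
    expect_null(out)
})
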