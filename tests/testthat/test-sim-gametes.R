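test_that("random pure-strict models have flat marginals and exact h2", {
    for (seed in 1:6) {
        m <- randomPureEpistasisModel(0.2, h2 = 0.2, prevalence = 0.25,
                                      seed = seed)
        w <- c(0.64, 0.32, 0.04)
        f <- penetranceTable(m)
        K <- prevalence(m)
        expect_equal(as.numeric(f %*% w), rep(K, 3), tolerance = 1e-12)
        expect_equal(as.numeric(t(w) %*% f), rep(K, 3), tolerance = 1e-12)
        expect_equal(computeHeritability(m), 0.2, tolerance = 1e-9)
        expect_true(all(f >= 0 & f <= 1))
    }
    # determinism
    m1 <- randomPureEpistasisModel(0.2, 0.1, seed = 42)
    m2 <- randomPureEpistasisModel(0.2, 0.1, seed = 42)
    expect_identical(penetranceTable(m1), penetranceTable(m2))
})

test_that("the XOR model at MAF 0.5 has K = 0.5, h2 = 1, detection 1", {
    m <- xorModel()
    expect_equal(prevalence(m), 0.5, tolerance = 1e-12)
    expect_equal(computeHeritability(m), 1, tolerance = 1e-12)
    expect_equal(edmProxy(m), 1, tolerance = 1e-12)
})

test_that("a constant penetrance table has zero h2 and detection 0.5", {
    m <- methods::new("PenetranceModel",
                      f = matrix(0.3, 3, 3), maf = 0.25, prevalence = 0.3,
                      h2 = 0, edm = 0.5, kind = "pure_pair")
    expect_equal(computeHeritability(m), 0, tolerance = 1e-12)
    expect_equal(edmProxy(m), 0.5, tolerance = 1e-12)
})

test_that("scaling penetrance deviations by c multiplies h2 by c^2", {
    m <- randomPureEpistasisModel(0.3, h2 = 0.1, seed = 9)
    K <- prevalence(m)
    f2 <- K + 0.5 * (penetranceTable(m) - K)
    m2 <- methods::new("PenetranceModel", f = f2, maf = 0.3,
                       prevalence = K, h2 = 0.1 * 0.25, edm = 0,
                       kind = "pure_pair")
    expect_equal(computeHeritability(m2), 0.1 * 0.25, tolerance = 1e-12)
})

test_that("ease-of-detection extremes follow an exhaustive scan", {
    pop <- samplePurePairModels(300, 0.2, h2 = 0.1, seed = 21)
    ex <- selectEdmExtremes(pop)
    proxies <- vapply(pop, edmProxy, numeric(1))
    expect_equal(edmProxy(ex$hard), min(proxies), tolerance = 0)
    expect_equal(edmProxy(ex$easy), max(proxies), tolerance = 0)
    expect_gte(edmProxy(ex$easy), edmProxy(ex$hard))
    expect_true(all(proxies >= 0.5 - 1e-12 & proxies <= 1 + 1e-12))
    # single-model population degenerates to (m, m); ties take the earliest
    one <- selectEdmExtremes(pop[1])
    expect_identical(penetranceTable(one$hard), penetranceTable(one$easy))
    expect_error(selectEdmExtremes(list()), "empty")
})

test_that("the additive main-effect locus hits its target h2 or reports
           infeasibility", {
    m <- mainEffectPenetrance(0.2, h2 = 0.2)
    w <- c(0.64, 0.32, 0.04)
    K <- m$prevalence
    expect_equal(sum(w * m$f), K, tolerance = 1e-12)
    expect_equal(sum(w * (m$f - K)^2) / (K * (1 - K)), 0.2,
                 tolerance = 1e-12)
    expect_true(all(m$f >= 0 & m$f <= 1))
    # additive direction at q = 0.2 is proportional to (-0.4, 0.6, 1.6)
    expect_equal(m$dev / m$dev[2] * 0.6, c(-0.4, 0.6, 1.6),
                 tolerance = 1e-12)
    # the rare minor homozygote caps the additive single-locus h2
    expect_error(mainEffectPenetrance(0.2, h2 = 0.9, prevalence = 0.25),
                 "infeasible")
})

test_that("the additive combination mixes penetrances and adds
           component variances", {
    epi <- randomPureEpistasisModel(0.2, h2 = 0.1, seed = 4)
    main <- mainEffectPenetrance(0.2, h2 = 0.1)
    cm <- combineWithMainEffect(epi, main, weight = 1 / 3)
    expect_true(all(cm@table >= 0 & cm@table <= 1))
    # weighted average of the component tables, cell by cell
    expect_equal(cm@table[2, 3, 1],
                 (2 / 3) * penetranceTable(epi)[2, 3] +
                 (1 / 3) * main$f[1], tolerance = 1e-12)
    # independent-locus deviations: variances add
    w <- c(0.64, 0.32, 0.04)
    W <- outer(w, w)
    K <- cm@prevalence
    ve <- (2 / 3)^2 * sum(W * (penetranceTable(epi) -
                               prevalence(epi))^2)
    vm <- (1 / 3)^2 * sum(w * main$dev^2)
    expect_equal(computeHeritability(cm), (ve + vm) / (K * (1 - K)),
                 tolerance = 1e-12)
    expect_equal(heritability(cm), computeHeritability(cm),
                 tolerance = 1e-12)
    expect_equal(sum(w * cm@mainDev), 0, tolerance = 1e-12)
    # degenerate weight: the pair alone
    cm0 <- combineWithMainEffect(epi, main, weight = 0)
    expect_equal(computeHeritability(cm0), 0.1, tolerance = 1e-9)
    expect_equal(cm0@table[, , 2], penetranceTable(epi),
                 tolerance = 1e-12)
})

test_that("gametes datasets are balanced, sized and deterministic", {
    epi <- randomPureEpistasisModel(0.2, h2 = 0.2, seed = 8)
    cm <- combineWithMainEffect(epi)
    d <- simulateGametesData(cm, nSnps = 30, nCases = 120, nControls = 80,
                             seed = 13)
    expect_identical(dim(genotypes(d)), c(200L, 30L))
    expect_identical(sum(phenotype(d) == 1L), 120L)
    expect_identical(causalIds(d), c("G1", "G2", "G3"))
    d2 <- simulateGametesData(cm, nSnps = 30, nCases = 120, nControls = 80,
                              seed = 13)
    expect_identical(genotypes(d2), genotypes(d))
    expect_error(simulateGametesData(cm, nSnps = 2), "nSnps")
})

test_that("shuffling moves the predictive loci but keeps the manifest", {
    epi <- randomPureEpistasisModel(0.2, h2 = 0.2, seed = 8)
    cm <- combineWithMainEffect(epi)
    d <- simulateGametesData(cm, nSnps = 40, nCases = 50, nControls = 50,
                             seed = 5, shuffle = TRUE)
    expect_identical(length(causalIds(d)), 3L)
    expect_true(all(causalIds(d) %in% featureIds(d)))
})

test_that("accepted cases/controls follow the class-conditional cell
           distributions of the penetrance model", {
    epi <- randomPureEpistasisModel(0.2, h2 = 0.4, seed = 31)
    cm <- combineWithMainEffect(epi)
    n <- 50000
    d <- simulateGametesData(cm, nSnps = 3, nCases = n, nControls = n,
                             seed = 17)
    g <- genotypes(d)
    y <- phenotype(d)
    w <- c(0.64, 0.32, 0.04)
    W3 <- outer(outer(w, w), w)
    f <- penetranceTable(cm)
    K <- prevalence(cm)
    pCase <- W3 * f / K
    pCtrl <- W3 * (1 - f) / (1 - K)
    cell <- (g[, 1]) + 3 * g[, 2] + 9 * g[, 3] + 1
    for (cl in c(1, 0)) {
        expected <- as.vector(if (cl == 1) pCase else pCtrl)
        obs <- tabulate(cell[y == cl], 27) / n
        se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
        expect_true(all(abs(obs - expected) < 4 * se + 1e-9))
    }
})
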