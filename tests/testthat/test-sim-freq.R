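test_that("the model grid assigns causal units as in the study design", {
    sp <- freqEffectSpec("case2_control2", 0.5)
    units <- lapply(sp@units, function(u) u$ids)
    expect_identical(units, list(c("G1", "G2"), c("G3", "G4"),
                                 c("G97", "G98"), c("G99", "G100")))
    expect_identical(vapply(sp@units, `[[`, "", "enriched"),
                     c("case", "case", "control", "control"))
    expect_identical(length(freqEffectSpec("3SNP", 0.1)@units), 3L)
    expect_error(freqEffectSpec("5SNP", 0.5), "unknown model")
})

test_that("the s -> 0 limit is the null: both groups at the HWE product", {
    sp <- freqEffectSpec("case1_control0", 0)
    p <- c(0.36, 0.48, 0.16)  # HWE at q = 0.4
    expect_equal(sp@units[[1]]$caseTable, outer(p, p), tolerance = 1e-12)
    expect_equal(sp@units[[1]]$controlTable, outer(p, p),
                 tolerance = 1e-12)
    spMain <- freqEffectSpec("1SNP", 0)
    expect_equal(spMain@units[[1]]$caseTable, p, tolerance = 1e-12)
})

test_that("main-effect mixture puts (1-s) HWE + s on the minor homozygote", {
    # hand arithmetic: s = 0.5, q = 0.4 -> P_case(2) = 0.5*0.16 + 0.5
    sp <- freqEffectSpec("1SNP", 0.5, maf = 0.4)
    expect_equal(sp@units[[1]]$caseTable[3], 0.58, tolerance = 1e-12)
    expect_equal(sum(sp@units[[1]]$caseTable), 1, tolerance = 1e-12)
    expect_equal(sp@units[[1]]$controlTable, c(0.36, 0.48, 0.16),
                 tolerance = 1e-12)
})

test_that("interaction mixture enriches the diagonal cells uniformly", {
    sp <- freqEffectSpec("case1_control0", 0.9, maf = 0.4)
    tab <- sp@units[[1]]$caseTable
    p <- c(0.36, 0.48, 0.16)
    expect_equal(diag(tab), 0.1 * p^2 + 0.9 / 3, tolerance = 1e-12)
    expect_equal(tab[1, 2], 0.1 * p[1] * p[2], tolerance = 1e-12)
    expect_equal(sum(tab), 1, tolerance = 1e-12)
})

test_that("simulated datasets meet quotas, order and determinism", {
    d <- simulateFreqData(freqEffectSpec("2SNP", 0.5), nSnps = 100,
                          nCases = 60, nControls = 40, seed = 11)
    expect_identical(dim(genotypes(d)), c(100L, 100L))
    expect_identical(sum(phenotype(d) == 1L), 60L)
    expect_identical(unname(phenotype(d)),
                     rep(c(1L, 0L), c(60L, 40L)))
    d2 <- simulateFreqData(freqEffectSpec("2SNP", 0.5), nSnps = 100,
                           nCases = 60, nControls = 40, seed = 11)
    expect_identical(genotypes(d2), genotypes(d))
    d3 <- simulateFreqData(freqEffectSpec("2SNP", 0.5), nSnps = 100,
                           nCases = 60, nControls = 40, seed = 12)
    expect_false(identical(genotypes(d3), genotypes(d)))
})

test_that("too few SNPs for the causal layout is an error", {
    expect_error(simulateFreqData(freqEffectSpec("case1_control1", 0.5),
                                  nSnps = 50, nCases = 10, nControls = 10),
                 "too small")
})

test_that("at s = 0 case and control genotype frequencies agree within
           binomial error", {
    n <- 25000
    d <- simulateFreqData(freqEffectSpec("case2_control2", 0), nSnps = 100,
                          nCases = n, nControls = n, seed = 3)
    g <- genotypes(d)
    y <- phenotype(d)
    for (j in c(1, 2, 50, 97, 100)) {
        for (gv in 0:2) {
            pc <- mean(g[y == 1, j] == gv)
            pn <- mean(g[y == 0, j] == gv)
            pool <- (pc + pn) / 2
            se <- sqrt(pool * (1 - pool) * 2 / n)
            expect_lt(abs(pc - pn), 4 * se + 1e-12)
        }
    }
})

test_that("noise SNPs sit at the target MAF and interaction marginals
           follow the analytic mixture", {
    n <- 25000
    s <- 0.6
    d <- simulateFreqData(freqEffectSpec("case1_control0", s, maf = 0.4),
                          nSnps = 20, nCases = n, nControls = n, seed = 5)
    g <- genotypes(d)
    y <- phenotype(d)
    # pooled MAF of a noise SNP
    maf <- mean(g[, 10]) / 2
    expect_lt(abs(maf - 0.4), 4 * sqrt(0.4 * 0.6 / (2 * 2 * n)))
    # single-locus marginal of a diagonal-enriched pair in cases:
    # (1-s) * HWE(g) + s/3 for every genotype
    p <- c(0.36, 0.48, 0.16)
    for (gv in 0:2) {
        pc <- mean(g[y == 1, "G1"] == gv)
        expected <- (1 - s) * p[gv + 1] + s / 3
        expect_lt(abs(pc - expected),
                  4 * sqrt(expected * (1 - expected) / n))
    }
})
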