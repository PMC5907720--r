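rankingOf <- function(ids, scores, method = "m") {
    FeatureRanking(method, stats::setNames(scores, ids))
}

test_that("topFraction takes round-half-up(p% of n) with a floor of one", {
    ids100 <- paste0("G", 1:100)
    r100 <- rankingOf(ids100, rev(seq_along(ids100)))
    expect_identical(topFraction(r100, 3), c("G1", "G2", "G3"))
    expect_identical(length(topFraction(r100, 10)), 10L)
    ids500 <- paste0("G", 1:500)
    r500 <- rankingOf(ids500, rev(seq_along(ids500)))
    expect_identical(length(topFraction(r500, 2)), 10L)
    ids10 <- paste0("G", 1:10)
    expect_identical(topFraction(rankingOf(ids10, 10:1), 5), "G1")
    # off the study grid: round half up, not banker's rounding
    expect_identical(length(topFraction(rankingOf(ids10, 10:1), 25)), 3L)
    expect_error(topFraction(r100, 0), "percentage")
    expect_error(topFraction(r100, 101), "percentage")
})

test_that("union and intersection follow set algebra with provenance", {
    r1 <- rankingOf(c("G1", "G2", "G3"), c(3, 2, 1), "a")
    r2 <- rankingOf(c("G1", "G2", "G3"), c(1, 3, 2), "b")
    sel <- collectiveUnion(list(r1, r2), 67)   # top 2 each
    expect_setequal(unionSet(sel), c("G1", "G2", "G3"))
    expect_setequal(intersectionSet(sel), "G2")
    expect_identical(sel@provenance$G1, "a")
    expect_setequal(sel@provenance$G2, c("a", "b"))
    # one method: union = intersection = its top set
    s1 <- collectiveUnion(list(r1), 67)
    expect_identical(unionSet(s1), intersectionSet(s1))
    expect_setequal(unionSet(s1), c("G1", "G2"))
})

test_that("mismatched feature universes are rejected", {
    r1 <- rankingOf(c("G1", "G2"), c(1, 2))
    r2 <- rankingOf(c("G1", "G3"), c(1, 2))
    expect_error(collectiveUnion(list(r1, r2), 50), "universe")
})

test_that("the union of m methods at p% holds between k and m*k
           features", {
    ids <- paste0("G", 1:100)
    rks <- withr::with_seed(9, lapply(1:4, function(i)
        rankingOf(ids, sample(100), paste0("m", i))))
    sel <- collectiveUnion(rks, 10)
    expect_gte(length(unionSet(sel)), 10L)
    expect_lte(length(unionSet(sel)), 40L)
    expect_true(all(vapply(perMethodSets(sel), length, 1L) == 10L))
})

test_that("the union grows monotonically with the percentage", {
    ids <- paste0("G", 1:50)
    rks <- withr::with_seed(10, lapply(1:3, function(i)
        rankingOf(ids, sample(50), paste0("m", i))))
    sizes <- vapply(c(2, 5, 10, 20, 50, 100), function(p)
        length(unionSet(collectiveUnion(rks, p))), 1L)
    expect_false(is.unsorted(sizes))
    # and the union always contains every per-method set
    sel <- collectiveUnion(rks, 10)
    for (s in perMethodSets(sel)) {
        expect_true(all(s %in% unionSet(sel)))
        expect_true(all(intersectionSet(sel) %in% s))
    }
})

test_that("union sensitivity dominates every member method by
           inclusion", {
    # property over random rankings and random truths
    ids <- paste0("G", 1:60)
    for (seed in 1:25) {
        rks <- withr::with_seed(seed, lapply(1:3, function(i)
            rankingOf(ids, stats::rnorm(60), paste0("m", i))))
        truth <- TruthManifest(list(list(
            ids = withr::with_seed(seed + 1000, sample(ids, 2)),
            enriched = "case")), "prop")
        sel <- collectiveUnion(rks, 10)
        su <- selectionSensitivity(unionSet(sel), truth)$sensitivity
        sm <- vapply(perMethodSets(sel), function(s)
            selectionSensitivity(s, truth)$sensitivity, numeric(1))
        expect_gte(su, max(sm))
    }
})
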