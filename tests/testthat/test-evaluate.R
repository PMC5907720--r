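truthOf <- function(...) {
    ids <- c(...)
    TruthManifest(lapply(ids, function(i)
        list(ids = i, enriched = "case")), "toy")
}

test_that("sensitivity, tp and fp follow the definition", {
    tr <- truthOf("G1", "G2")
    s <- selectionSensitivity(c("G1", "G2", "G50"), tr)
    expect_equal(s$sensitivity, 1)
    expect_identical(c(s$tp, s$fp), c(2L, 1L))
    expect_equal(selectionSensitivity(c("G9", "G8"), tr)$sensitivity, 0)
    s2 <- selectionSensitivity(c("G1", "G3"),
                               truthOf("G1", "G2", "G3", "G4"))
    expect_equal(s2$sensitivity, 0.5)
    expect_error(selectionSensitivity("G1",
        methods::new("TruthManifest", causalIds = character(),
                     modelName = "x", effectStructure = list())),
        "empty truth")
})

test_that("replicate aggregation averages within groups", {
    rows <- data.frame(model = "m", method = c("a", "a", "b"),
                       percentage = 10, replicate = c(1, 2, 1),
                       sensitivity = c(1, 0.5, 0.25), tp = c(2, 1, 1),
                       fp = c(0, 1, 3))
    agg <- aggregateReplicates(rows)
    a <- agg[agg$method == "a", ]
    expect_equal(a$sensitivity, 0.75)
    expect_equal(a$tp, 1.5)
    expect_identical(a$n, 2L)
    expect_identical(a$replicate, "mean")
    b <- agg[agg$method == "b", ]
    expect_equal(b$sensitivity, 0.25)   # single replicate: unchanged
    expect_identical(b$n, 1L)
})

test_that("overlap counts partition the union", {
    oc <- overlapCounts(list(a = c("x", "y"), b = c("y", "z")))
    expect_identical(oc[["a"]], 1L)
    expect_identical(oc[["b"]], 1L)
    expect_identical(oc[["a&b"]], 1L)
    same <- overlapCounts(list(a = c("x", "y"), b = c("x", "y"),
                               c = c("x", "y")))
    expect_identical(unname(same[["a&b&c"]]), 2L)
    expect_identical(sum(same), 2L)
    disj <- overlapCounts(list(a = "x", b = "y", c = "z"))
    expect_identical(sum(disj > 0), 3L)
    expect_identical(sum(disj), 3L)
    expect_error(overlapCounts(list(a = "x")), "2-4")
    expect_error(overlapCounts(rep(list("x"), 5)), "2-4")
})

smallFreqConfig <- function(seed = 5) list(
    experiment = "freq", models = c("1SNP", "case1_control0"),
    signals = 0.9, nSnps = 20, nCases = 100, nControls = 100,
    methods = c("mdr", "multisurf_star"), percentages = c(5, 10),
    replicates = 2, seed = seed)

test_that("the benchmark runner emits a complete long-format table with
           union dominance in every row", {
    out <- runBenchmark(smallFreqConfig())
    res <- out$results
    # 2 models x 2 reps x 2 percentages x (2 methods + union)
    expect_identical(nrow(res), 2L * 2L * 2L * 3L)
    expect_true(all(res$tp + res$fp == res$n_selected))
    expect_true(all(res$sensitivity >= 0 & res$sensitivity <= 1))
    expect_length(out$errors, 0L)
    for (key in unique(interaction(res$model, res$percentage,
                                   res$replicate))) {
        grp <- res[interaction(res$model, res$percentage,
                               res$replicate) == key, ]
        expect_gte(grp$sensitivity[grp$method == "union"],
                   max(grp$sensitivity[grp$method != "union"]))
    }
    expect_true(all(c("model", "method", "percentage", "replicate",
                      "sensitivity", "tp", "fp") %in% colnames(res)))
})

test_that("a fixed master seed reproduces the benchmark bitwise", {
    out1 <- runBenchmark(smallFreqConfig(seed = 31))
    out2 <- runBenchmark(smallFreqConfig(seed = 31))
    expect_identical(out1$results, out2$results)
    out3 <- runBenchmark(smallFreqConfig(seed = 32))
    expect_false(identical(out1$results, out3$results))
})

test_that("the gametes benchmark pools true positives per architecture
           and tabulates overlaps", {
    cfg <- list(experiment = "gametes", h2 = c(0.2, 0.4),
                architectures = c("easy", "hard"), candidates = 200,
                nSnps = 20, nCases = 150, nControls = 150,
                methods = c("mdr", "multisurf_star"),
                percentages = 10, replicates = 2, seed = 8)
    out <- runBenchmark(cfg)
    expect_identical(dim(out$pooledTruePositives), c(2L, 1L))
    # pooled counts merge each heritability's own 3 causal loci
    expect_true(all(out$pooledTruePositives >= 0 &
                    out$pooledTruePositives <= 6))
    expect_identical(nrow(out$results), 2L * 2L * 2L * 3L)
    oc <- out$overlap[["easy"]][["10"]]
    expect_setequal(names(oc),
                    c("mdr", "multisurf_star", "mdr&multisurf_star"))
    # regions partition the pooled union: counts sum to its size
    pooled <- list(mdr = character(), multisurf_star = character())
    for (key in grep("easy", names(out$selections), value = TRUE)) {
        sel <- out$selections[[key]]$selections[["10"]]
        h2tag <- sub("^gametes_easy_h([0-9.]+)_r.*$", "\\1", key)
        for (m in names(pooled))
            pooled[[m]] <- union(pooled[[m]],
                paste0(h2tag, ":", perMethodSets(sel)[[m]]))
    }
    expect_identical(sum(oc), length(unique(unlist(pooled))))
})
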