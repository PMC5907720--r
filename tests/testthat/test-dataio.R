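test_that("gametes_tsv and plink_raw round-trip a dataset exactly", {
    d <- simulateFreqData(freqEffectSpec("2SNP", 0.5), nSnps = 12,
                          nCases = 15, nControls = 15, seed = 7)
    for (dialect in c("gametes_tsv", "plink_raw")) {
        f <- withr::local_tempfile(fileext = ".txt")
        writeGenotypes(d, f, dialect)
        d2 <- readGenotypes(f, dialect)
        expect_identical(genotypes(d2), genotypes(d))
        expect_identical(unname(phenotype(d2)), unname(phenotype(d)))
        expect_identical(featureIds(d2), featureIds(d))
        # truth travels through the sidecar manifest
        tr <- readTruthManifest(paste0(f, ".truth.yaml"))
        expect_setequal(causalIds(tr), causalIds(d))
        truthManifest(d2) <- tr
        expect_identical(causalIds(d2), causalIds(d))
    }
})

test_that("gametes_tsv header puts feature IDs before the Class column", {
    d <- simulateFreqData(freqEffectSpec("1SNP", 0.5), nSnps = 5,
                          nCases = 4, nControls = 4, seed = 1)
    f <- withr::local_tempfile(fileext = ".txt")
    writeGenotypes(d, f, "gametes_tsv")
    header <- strsplit(readLines(f, n = 1), "\t")[[1]]
    expect_identical(header, c(paste0("G", 1:5), "Class"))
})

test_that("a small gametes_tsv fixture parses to the written phenotype", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("G1\tG2\tClass",
                 "0\t1\t0", "2\t0\t0", "1\t1\t1", "0\t2\t1"), f)
    d <- readGenotypes(f, "gametes_tsv")
    expect_identical(unname(phenotype(d)), c(0L, 0L, 1L, 1L))
    expect_identical(genotypes(d)[, "G1"],
                     stats::setNames(c(0L, 2L, 1L, 0L), paste0("S", 1:4)))
})

test_that("invalid genotype values are rejected with cell coordinates", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("G1\tG2\tClass", "0\t1\t0", "3\t0\t1"), f)
    expect_error(readGenotypes(f, "gametes_tsv"), "row 2.*G1")
})

test_that("a missing Class column and duplicate IDs are format errors", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("G1\tG2", "0\t1", "1\t0"), f)
    expect_error(readGenotypes(f, "gametes_tsv"), "Class")
    writeLines(c("G1\tG1\tClass", "0\t1\t0", "1\t0\t1"), f)
    expect_error(readGenotypes(f, "gametes_tsv"), "duplicate feature")
})

test_that("plink_raw maps PHENOTYPE 1/2 to control/case", {
    f <- withr::local_tempfile(fileext = ".raw")
    writeLines(c("FID IID PAT MAT SEX PHENOTYPE G1 G2",
                 "F1 I1 0 0 0 1 0 2",
                 "F2 I2 0 0 0 2 1 1"), f)
    d <- readGenotypes(f, "plink_raw")
    expect_identical(unname(phenotype(d)), c(0L, 1L))
    expect_identical(sampleIds(d), c("I1", "I2"))
})

test_that("dataset validation rejects out-of-range values and bad labels", {
    g <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
    expect_error(SnpDataset(g, status = c(0, 2)), "status")
    expect_error(SnpDataset(g, status = c(1, 1)), "control")
    g[1, 1] <- 5L
    expect_error(SnpDataset(g, status = c(0, 1)), "0, 1 or 2")
})

test_that("rankings round-trip with full precision and stable tie ranks", {
    r <- FeatureRanking("toy",
        c(G1 = 1 / 3, G2 = 0.25, G3 = 1 / 3, G4 = exp(1)))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeRanking(r, f)
    r2 <- readRanking(f, method = "toy")
    expect_identical(rankedFeatures(r2), c("G4", "G1", "G3", "G2"))
    expect_equal(featureScores(r2)[rankedFeatures(r)],
                 featureScores(r)[rankedFeatures(r)], tolerance = 0)
    df <- utils::read.table(f, header = TRUE, sep = "\t")
    expect_identical(df$rank, 1:4)
})

test_that("a rank column inconsistent with the scores is rejected", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("feature_id\tscore\trank",
                 "G1\t0.1\t1", "G2\t0.9\t2"), f)
    expect_error(readRanking(f), "inconsistent with scores")
    writeLines(c("feature_id\tscore\trank",
                 "G1\t0.9\t2", "G2\t0.1\t1"), f)
    expect_error(readRanking(f), "1..n")
})
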