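## Experiment-1 style simulator: balanced case/control datasets in which
## causal SNPs (singletons or pairs) have different (joint) genotype
## frequencies in cases versus controls, sampled with replacement.
##
## Baseline genotype distribution is Hardy-Weinberg at MAF q,
## P_HWE = ((1-q)^2, 2q(1-q), q^2) for codes (0, 1, 2). Enrichment mixes
## the baseline with a point mass:
##   main effect (case-enriched):  P_case(g)  = (1-s) P_HWE(g) + s w(g)
##   interacting pair, group X:    P_X(g1,g2) = (1-s) P_HWE(g1) P_HWE(g2)
##                                              + s Diag(g1,g2)
## where w defaults to a point mass on the minor homozygote (g = 2) and
## Diag is uniform over the diagonal cells {(0,0),(1,1),(2,2)} (the
## "diagonal" architecture). The unenriched group keeps the independent
## HWE product, and s = 0 reduces to the null.

.freqModels <- c("1SNP", "2SNP", "3SNP", "4SNP", "case1_control0",
                 "case1_control1", "case2_control0", "case2_control2")

#' Build the genotype-frequency tables of a frequency-shift model
#'
#' @param modelName one of \code{"1SNP"}..\code{"4SNP"} (1-4 case-enriched
#'   main-effect SNPs, G1..G4) or the interaction layouts
#'   \code{"case1_control0"} (case pair G1-G2),
#'   \code{"case1_control1"} (adds control pair G99-G100),
#'   \code{"case2_control0"} (case pairs G1-G2, G3-G4),
#'   \code{"case2_control2"} (adds control pairs G97-G98, G99-G100).
#' @param signal mixing weight s in [0, 1); the study grid uses
#'   0.1, 0.5, 0.9.
#' @param maf baseline minor allele frequency (default 0.4).
#' @param mainWeights length-3 enrichment profile for main-effect units;
#'   the default point mass on g = 2 targets the minor homozygote. Must be
#'   non-negative and sum to 1.
#' @return A \linkS4class{FreqEffectSpec}.
#' @examples
#' sp <- freqEffectSpec("1SNP", signal = 0.5)
#' sp@units[[1]]$caseTable  # (1-s) HWE + s * point mass on g = 2
#' @export
freqEffectSpec <- function(modelName, signal, maf = 0.4,
                           mainWeights = c(0, 0, 1)) {
    if (!modelName %in% .freqModels)
        stopf("unknown model '%s' (expected one of: %s)", modelName,
              paste(.freqModels, collapse = ", "))
    if (signal < 0 || signal >= 1)
        stopf("signal must lie in [0, 1)")
    if (any(mainWeights < 0) || abs(sum(mainWeights) - 1) > 1e-12)
        stopf("mainWeights must be non-negative and sum to 1")
    p <- hweProbs(maf)
    s <- signal
    mainUnit <- function(id) list(
        ids = id, enriched = "case",
        caseTable = (1 - s) * p + s * mainWeights,
        controlTable = p)
    pairUnit <- function(ids, group) {
        base <- outer(p, p)
        diag3 <- diag(3) / 3
        enr <- (1 - s) * base + s * diag3
        list(ids = ids, enriched = group,
             caseTable = if (group == "case") enr else base,
             controlTable = if (group == "control") enr else base)
    }
    units <- switch(modelName,
        "1SNP" = list(mainUnit("G1")),
        "2SNP" = lapply(c("G1", "G2"), mainUnit),
        "3SNP" = lapply(c("G1", "G2", "G3"), mainUnit),
        "4SNP" = lapply(c("G1", "G2", "G3", "G4"), mainUnit),
        "case1_control0" = list(pairUnit(c("G1", "G2"), "case")),
        "case1_control1" = list(pairUnit(c("G1", "G2"), "case"),
                                pairUnit(c("G99", "G100"), "control")),
        "case2_control0" = list(pairUnit(c("G1", "G2"), "case"),
                                pairUnit(c("G3", "G4"), "case")),
        "case2_control2" = list(pairUnit(c("G1", "G2"), "case"),
                                pairUnit(c("G3", "G4"), "case"),
                                pairUnit(c("G97", "G98"), "control"),
                                pairUnit(c("G99", "G100"), "control")))
    obj <- new("FreqEffectSpec", modelName = modelName, signal = signal,
               maf = maf, units = units)
    validObject(obj)
    obj
}

# draw n genotypes (or genotype pairs) from a unit's table for one group
.drawUnit <- function(unit, group, n) {
    tab <- if (group == "case") unit$caseTable else unit$controlTable
    if (length(unit$ids) == 1L) {
        matrix(sample(0:2, n, replace = TRUE, prob = tab), ncol = 1)
    } else {
        cell <- sample(9L, n, replace = TRUE, prob = as.vector(tab))
        # column-major 3x3: cell = g1 + 3*g2 + 1
        cbind((cell - 1L) %% 3L, (cell - 1L) %/% 3L)
    }
}

#' Simulate a frequency-shift case/control dataset
#'
#' Causal columns are drawn i.i.d. per sample from the group-appropriate
#' frequency table; every non-causal column is drawn i.i.d. from the HWE
#' baseline identically in both groups. Cases occupy the first
#' \code{nCases} rows.
#'
#' @param spec a \linkS4class{FreqEffectSpec} from [freqEffectSpec()].
#' @param nSnps total number of SNPs (study sizes: 100 or 500).
#' @param nCases,nControls class quotas (study size: 2000 each).
#' @param seed RNG seed; a fixed seed reproduces the dataset exactly.
#' @param replicate replicate index recorded in the provenance; replicate
#'   r of a series should be simulated with seed \code{seed + r} (or via
#'   [runBenchmark()]'s derived seeds).
#' @return A \linkS4class{SnpDataset} with truth manifest attached.
#' @examples
#' d <- simulateFreqData(freqEffectSpec("2SNP", 0.5), nSnps = 100,
#'                       nCases = 50, nControls = 50, seed = 1)
#' causalIds(d)
#' @export
simulateFreqData <- function(spec, nSnps = 100, nCases = 2000,
                             nControls = 2000, seed = 1, replicate = 1) {
    validObject(spec)
    ids <- paste0("G", seq_len(nSnps))
    causal <- unlist(lapply(spec@units, `[[`, "ids"))
    if (anyDuplicated(causal))
        stopf("model '%s' assigns a SNP to two causal units", spec@modelName)
    if (!all(causal %in% ids))
        stopf("nSnps = %d is too small for model '%s' (needs %s)",
              nSnps, spec@modelName, paste(causal, collapse = ", "))
    if (nCases < 1 || nControls < 1) stopf("class quotas must be >= 1")
    n <- nCases + nControls
    withSeed(seed, {
        g <- matrix(sample(0:2, n * nSnps, replace = TRUE,
                           prob = hweProbs(spec@maf)), nrow = n)
        colnames(g) <- ids
        caseRows <- seq_len(nCases)
        ctrlRows <- nCases + seq_len(nControls)
        for (u in spec@units) {
            g[caseRows, u$ids] <- .drawUnit(u, "case", nCases)
            g[ctrlRows, u$ids] <- .drawUnit(u, "control", nControls)
        }
        truth <- TruthManifest(
            lapply(spec@units, function(u) u[c("ids", "enriched")]),
            modelName = sprintf("%s_s%g", spec@modelName, spec@signal))
        SnpDataset(g, status = rep(c(1L, 0L), c(nCases, nControls)),
                   truth = truth, generator = "freq", seed = seed,
                   replicate = replicate)
    })
}
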