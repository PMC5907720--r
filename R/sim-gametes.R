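## Experiment-2 style simulator: random pure-strict two-locus epistasis
## penetrance models at fixed MAF and heritability, additively combined
## with a one-locus main effect, stratified into easy/hard architectures
## by an ease-of-detection score, then sampled into balanced case/control
## datasets by rejection sampling on the penetrance.

# Orthonormal basis of the 4-dimensional space of 3x3 deviation tables with
# zero HWE-weighted row and column marginals (the pure-strict constraint set:
# 6 marginal constraints of rank 5).
.pureNullBasis <- function(q) {
    w <- hweProbs(q)
    A <- matrix(0, 6, 9)
    for (g1 in 1:3)
        for (g2 in 1:3) {
            k <- g1 + 3 * (g2 - 1)
            A[g1, k] <- w[g2]        # row marginals
            A[3 + g2, k] <- w[g1]    # column marginals
        }
    e <- eigen(crossprod(A), symmetric = TRUE)
    B <- e$vectors[, e$values < 1e-10 * max(e$values), drop = FALSE]
    stopifnot(ncol(B) == 4L)
    B
}

.h2FromDeviation <- function(d, W, K) sum(W * d^2) / (K * (1 - K))

.newPureModel <- function(f, q, K) {
    w <- hweProbs(q)
    W <- outer(w, w)
    h2 <- .h2FromDeviation(f - K, W, K)
    m <- new("PenetranceModel", f = f, maf = q, prevalence = K, h2 = h2,
             edm = NA_real_, kind = "pure_pair")
    m@edm <- edmProxy(m)
    validObject(m)
    m
}

#' Draw a random pure-strict two-locus epistasis model
#'
#' Samples a deviation table uniformly (isotropic Gaussian direction) in the
#' 4-dimensional null space of the zero-marginal-penetrance constraints,
#' scales it so the heritability equals \code{h2} exactly, and sets
#' f = K + d. Draws are rejected and redrawn while any penetrance leaves
#' [0, 1], so every returned model is a valid pure-strict model: all six
#' single-locus marginal penetrances equal the prevalence K.
#'
#' @param maf minor allele frequency q of both loci (study value 0.2).
#' @param h2 target heritability (study grid 0.1, 0.2, 0.4).
#' @param prevalence K in (0, 1); the default adapts to \code{h2}
#'   (0.25 at h2 = 0.1 rising to 0.4 at h2 = 0.4), since high-h2
#'   pure-strict tables need deviation room on both sides of K.
#' @param seed RNG seed.
#' @param maxRetries rejection-sampling cap before declaring the target
#'   infeasible.
#' @return A \linkS4class{PenetranceModel} of kind \code{"pure_pair"}.
#' @examples
#' m <- randomPureEpistasisModel(0.2, h2 = 0.2, seed = 3)
#' heritability(m)   # 0.2 exactly (to numerical precision)
#' @export
randomPureEpistasisModel <- function(maf, h2, prevalence = NULL, seed = 1,
                                     maxRetries = 10000) {
    if (h2 <= 0 || h2 >= 1) stopf("h2 must lie in (0, 1)")
    if (is.null(prevalence)) prevalence <- .defaultPairPrevalence(h2)
    if (prevalence <= 0 || prevalence >= 1)
        stopf("prevalence must lie in (0, 1)")
    B <- .pureNullBasis(maf)
    w <- hweProbs(maf)
    W <- outer(w, w)
    K <- prevalence
    withSeed(seed, {
        for (i in seq_len(maxRetries)) {
            d <- matrix(B %*% stats::rnorm(4), 3, 3)
            v <- .h2FromDeviation(d, W, K)
            if (v < 1e-300) next
            f <- K + d * sqrt(h2 / v)
            if (all(f >= 0) && all(f <= 1))
                return(.newPureModel(f, maf, K))
        }
        stopf(paste0("no pure-strict model with h2 = %g found at ",
                     "MAF = %g, K = %g after %d draws (target infeasible?)"),
              h2, maf, K, maxRetries)
    })
}

#' Draw a population of random pure-strict models
#'
#' Vectorised batch version of [randomPureEpistasisModel()] used to scan
#' for ease-of-detection extremes.
#'
#' @inheritParams randomPureEpistasisModel
#' @param n number of accepted models to return.
#' @return List of \linkS4class{PenetranceModel}s.
#' @export
samplePurePairModels <- function(n, maf, h2, prevalence = NULL, seed = 1) {
    if (is.null(prevalence)) prevalence <- .defaultPairPrevalence(h2)
    B <- .pureNullBasis(maf)
    w <- hweProbs(maf)
    W <- outer(w, w)
    Wv <- as.vector(W)
    K <- prevalence
    out <- vector("list", n)
    got <- 0L
    withSeed(seed, {
        guard <- 0L
        while (got < n) {
            guard <- guard + 1L
            if (guard > 10000L)
                stopf("model population at h2 = %g appears infeasible", h2)
            m <- min(4096L, 4L * (n - got) + 64L)
            D <- B %*% matrix(stats::rnorm(4L * m), 4L, m)
            v <- colSums(Wv * D^2) / (K * (1 - K))
            ok <- v > 1e-300
            Fm <- K + sweep(D[, ok, drop = FALSE], 2,
                            sqrt(h2 / v[ok]), `*`)
            feas <- which(colSums(Fm >= 0) == 9L & colSums(Fm <= 1) == 9L)
            for (j in feas) {
                if (got >= n) break
                got <- got + 1L
                out[[got]] <- .newPureModel(matrix(Fm[, j], 3, 3), maf, K)
            }
        }
    })
    out
}

#' Heritability of a penetrance model
#'
#' The penetrance-based (broad-sense, under HWE) heritability: the
#' HWE-weighted variance of the penetrance about the prevalence K,
#' divided by K(1 - K).
#'
#' @param model a \linkS4class{PenetranceModel} or
#'   \linkS4class{CombinedModel}.
#' @return Scalar heritability.
#' @examples
#' computeHeritability(xorModel())  # 1
#' @export
computeHeritability <- function(model) {
    if (is(model, "CombinedModel")) {
        q <- model@epi@maf
        w <- hweProbs(q)
        W3 <- outer(outer(w, w), w)
        K <- model@prevalence
        if (K <= 0 || K >= 1) stopf("heritability undefined for K in {0,1}")
        return(sum(W3 * (model@table - K)^2) / (K * (1 - K)))
    }
    w <- hweProbs(model@maf)
    K <- model@prevalence
    if (K <= 0 || K >= 1) stopf("heritability undefined for K in {0,1}")
    sum(outer(w, w) * (model@f - K)^2) / (K * (1 - K))
}

#' Ease-of-detection score of a two-locus model
#'
#' The analytic Bayes-optimal two-locus balanced accuracy,
#' BA* = 0.5 + 0.25 * sum over cells |P(cell|case) - P(cell|control)|,
#' with class-conditional cell masses w(g1) w(g2) f / K and
#' w(g1) w(g2) (1 - f) / (1 - K). Ranges from 0.5 (undetectable) to 1;
#' higher means easier to detect. Used operationally to stratify equal-h2
#' model populations into hard (minimum) and easy (maximum) architectures.
#'
#' @param model a \linkS4class{PenetranceModel}.
#' @return Scalar in [0.5, 1].
#' @examples
#' edmProxy(xorModel())  # 1: classes are perfectly separable
#' @export
edmProxy <- function(model) {
    w <- hweProbs(model@maf)
    W <- outer(w, w)
    K <- model@prevalence
    pc <- W * model@f / K
    pn <- W * (1 - model@f) / (1 - K)
    0.5 + 0.25 * sum(abs(pc - pn))
}

#' The XOR penetrance model at MAF 0.5
#'
#' A classical fully-penetrant pure epistasis example: f = 1 on the cells
#' where exactly one locus is heterozygous, 0 elsewhere. At MAF 0.5 it has
#' prevalence 0.5, heritability 1 and ease-of-detection 1.
#'
#' @return A \linkS4class{PenetranceModel}.
#' @export
xorModel <- function() {
    f <- matrix(0, 3, 3)
    f[1, 2] <- f[2, 1] <- f[2, 3] <- f[3, 2] <- 1
    .newPureModel(f, q = 0.5, K = 0.5)
}

#' Pick the ease-of-detection extremes of a model population
#'
#' @param population non-empty list of \linkS4class{PenetranceModel}s at
#'   identical (MAF, h2, K).
#' @return List with elements \code{hard} (minimum score, the hard-to-detect
#'   architecture) and \code{easy} (maximum score); ties resolve to the
#'   earliest index.
#' @export
selectEdmExtremes <- function(population) {
    if (length(population) == 0L) stopf("empty model population")
    s <- vapply(population, function(m) m@edm, numeric(1))
    list(hard = population[[which.min(s)]],
         easy = population[[which.max(s)]])
}

# unit-HWE-variance additive deviation for the third locus: d(g) prop (g-2q)
.mainDirection <- function(q) {
    w <- hweProbs(q)
    d <- (0:2) - 2 * q
    d / sqrt(sum(w * d^2))
}

# feasibility-motivated prevalence defaults: pure-strict pairs at high h2
# need room on both sides of K (at MAF 0.2 the achievable pair h2 tops out
# near 0.33 at K = 0.25 but near 0.45 at K = 0.4), while an additive
# single-locus effect caps at h2 = (1-K)/(8K) at MAF 0.2, so its K must
# shrink as h2 grows
.defaultPairPrevalence <- function(h2) min(0.45, max(0.25, 0.25 +
                                                     0.5 * (h2 - 0.1)))
.defaultMainPrevalence <- function(h2) min(0.25, 1 / (1 + 8.8 * h2))

#' An additive single-locus penetrance model
#'
#' Penetrance linear in the allele count: f(g) = K + c (g - 2q), with c
#' chosen so the model's heritability equals \code{h2}. The proportionality
#' constant keeps all three penetrances in [0, 1] or the target is
#' declared infeasible (at MAF q = 0.2 the additive single-locus h2 caps
#' at (1 - K) / (8 K), driven by the rare minor homozygote).
#'
#' @param maf minor allele frequency q.
#' @param h2 target heritability of the locus.
#' @param prevalence K; default adapts to \code{h2} so the target stays
#'   feasible.
#' @return List with \code{f} (length-3 penetrance vector), \code{dev}
#'   (zero-HWE-mean deviation f - K), \code{maf}, \code{prevalence},
#'   \code{h2}.
#' @examples
#' mainEffectPenetrance(0.2, h2 = 0.2)$f
#' @export
mainEffectPenetrance <- function(maf, h2, prevalence = NULL) {
    if (is.null(prevalence)) prevalence <- .defaultMainPrevalence(h2)
    K <- prevalence
    if (K <= 0 || K >= 1) stopf("prevalence must lie in (0, 1)")
    dm <- .mainDirection(maf)            # unit HWE variance
    cm <- sqrt(h2 * K * (1 - K))
    f <- K + cm * dm
    if (any(f < 0) || any(f > 1))
        stopf(paste0("no additive single-locus model with h2 = %g at ",
                     "MAF = %g, K = %g: penetrances leave [0, 1] ",
                     "(infeasible target)"), h2, maf, K)
    list(f = f, dev = cm * dm, maf = maf, prevalence = K, h2 = h2)
}

#' Additively combine a pure epistatic pair with a third-locus main effect
#'
#' GAMETES-style additive combination: the 27-cell penetrance is the
#' weighted average
#' f(g1, g2, g3) = (1 - weight) f_epi(g1, g2) + weight f_main(g3),
#' which always stays in [0, 1]. Equivalently
#' f = K + ce (f_epi - K_epi) + cm dMain(g3) with ce = 1 - weight,
#' cm = weight and K the same mixture of the component prevalences.
#' Because the two deviation components sit on independent loci and are
#' zero-mean under HWE, their variances add: the combined heritability is
#' (ce^2 V_epi + cm^2 V_main) / (K (1 - K)), computed and stored.
#'
#' @param epi a pure-pair \linkS4class{PenetranceModel}.
#' @param main an additive single-locus model from
#'   [mainEffectPenetrance()]; default: same MAF and nominal h2 as the
#'   pair.
#' @param weight mixing weight of the main-effect component in [0, 1)
#'   (default 1/3: one of the three predictive loci).
#' @return A \linkS4class{CombinedModel}.
#' @examples
#' epi <- randomPureEpistasisModel(0.2, h2 = 0.1, seed = 4)
#' cm <- combineWithMainEffect(epi, weight = 1 / 3)
#' computeHeritability(cm)
#' @export
combineWithMainEffect <- function(epi,
                                  main = mainEffectPenetrance(epi@maf,
                                                              epi@h2),
                                  weight = 1/3) {
    if (weight < 0 || weight >= 1)
        stopf("weight must lie in [0, 1)")
    if (abs(main$maf - epi@maf) > 1e-12)
        stopf("component models must share the MAF")
    ce <- 1 - weight
    cm <- weight
    K <- ce * epi@prevalence + cm * main$prevalence
    de <- epi@f - epi@prevalence
    tab <- array(0, c(3, 3, 3))
    for (g3 in 1:3) tab[, , g3] <- K + ce * de + cm * main$dev[g3]
    obj <- new("CombinedModel", epi = epi, mainDev = main$dev,
               ce = ce, cm = cm, prevalence = K, h2Total = 0,
               table = tab)
    obj@h2Total <- computeHeritability(obj)
    validObject(obj)
    obj
}

#' Simulate a GAMETES-style case/control dataset
#'
#' All SNPs (predictive and noise alike) are drawn i.i.d. from HWE at the
#' model's MAF; disease status is assigned by the 27-cell penetrance of the
#' three predictive loci, and individuals are accepted into whichever class
#' quota is unfilled (rejection sampling), so the dataset is balanced
#' exactly. Predictive loci occupy columns 1-3 (unless \code{shuffle}) and
#' are recorded in the truth manifest.
#'
#' @param model a \linkS4class{CombinedModel}.
#' @param nSnps number of SNPs (study value 100: 3 predictive + 97 noise).
#' @param nCases,nControls class quotas (study values 1000 each).
#' @param seed RNG seed.
#' @param modelName truth-manifest model name.
#' @param shuffle permute the columns (predictive loci land at random
#'   positions, still recorded in the manifest).
#' @param replicate replicate index recorded in the provenance.
#' @return A \linkS4class{SnpDataset} with truth attached.
#' @export
simulateGametesData <- function(model, nSnps = 100, nCases = 1000,
                                nControls = 1000, seed = 1,
                                modelName = "gametes", shuffle = FALSE,
                                replicate = 1) {
    if (nSnps < 3L) stopf("nSnps must be >= 3")
    q <- model@epi@maf
    p <- hweProbs(q)
    f <- model@table
    caseG <- matrix(0L, 0L, 3L)
    ctrlG <- matrix(0L, 0L, 3L)
    withSeed(seed, {
        while (nrow(caseG) < nCases || nrow(ctrlG) < nControls) {
            m <- 4096L
            g <- matrix(sample(0:2, 3L * m, replace = TRUE, prob = p),
                        m, 3L)
            pen <- f[cbind(g[, 1] + 1L, g[, 2] + 1L, g[, 3] + 1L)]
            isCase <- stats::runif(m) < pen
            needCase <- nCases - nrow(caseG)
            needCtrl <- nControls - nrow(ctrlG)
            if (needCase > 0L) {
                add <- utils::head(which(isCase), needCase)
                caseG <- rbind(caseG, g[add, , drop = FALSE])
            }
            if (needCtrl > 0L) {
                add <- utils::head(which(!isCase), needCtrl)
                ctrlG <- rbind(ctrlG, g[add, , drop = FALSE])
            }
        }
        n <- nCases + nControls
        G <- matrix(sample(0:2, n * nSnps, replace = TRUE, prob = p),
                    n, nSnps)
        G[, 1:3] <- rbind(caseG, ctrlG)
        ids <- paste0("G", seq_len(nSnps))
        predictive <- c("G1", "G2", "G3")
        if (shuffle) {
            perm <- sample(nSnps)
            G <- G[, perm, drop = FALSE]
            predictive <- ids[match(1:3, perm)]
        }
        colnames(G) <- ids
        truth <- TruthManifest(
            list(list(ids = predictive[1:2], enriched = "case"),
                 list(ids = predictive[3], enriched = "case")),
            modelName = modelName)
        SnpDataset(G, status = rep(c(1L, 0L), c(nCases, nControls)),
                   truth = truth, generator = "gametes", seed = seed,
                   replicate = replicate)
    })
}
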