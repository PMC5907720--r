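## Exhaustive one- and two-locus multifactor dimensionality reduction,
## used as a filter: every model is scored by training balanced accuracy
## and each feature inherits the best accuracy among models containing it.
##
## Cell labelling rule: a genotype cell is high-risk iff its case:control
## ratio strictly exceeds the dataset-wide ratio, i.e.
## cases(cell) * nControls > controls(cell) * nCases; empty cells and exact
## ties are low-risk (conservative, deterministic).
##
## The two-way scan is computed with 9 + 9 indicator cross-products
## (cases and controls separately), so all C(p,2) models are scored with
## dense matrix algebra rather than per-pair loops.

.mdrCounts <- function(X, y) {
    lapply(0:2, function(g) {
        M <- (X == g) * 1
        list(case = M * y, ctrl = M * (1 - y))
    })
}

#' Rank features by exhaustive MDR
#'
#' Evaluates all p one-locus and choose(p, 2) two-locus MDR models without
#' cross-validation and scores each feature by the maximum training
#' balanced accuracy over the models that contain it.
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param maxOrder 1 (main effects only) or 2 (default; adds all pairs).
#' @return A list with \code{ranking} (a \linkS4class{FeatureRanking},
#'   method \code{"mdr"}) and \code{models} (data.frame of all evaluated
#'   models -- columns \code{locus1}, \code{locus2} (NA for one-way),
#'   \code{ba} -- sorted by descending balanced accuracy). Use
#'   [mdrModel()] to materialise any single model with its cell labels.
#' @examples
#' d <- simulateFreqData(freqEffectSpec("1SNP", 0.9), nSnps = 20,
#'                       nCases = 100, nControls = 100, seed = 1)
#' r <- mdrRank(d)
#' rankedFeatures(r$ranking)[1]   # "G1"
#' @export
mdrRank <- function(dataset, maxOrder = 2) {
    stopifnot(maxOrder %in% 1:2)
    X <- genotypes(dataset)
    y <- as.numeric(phenotype(dataset))
    ids <- featureIds(dataset)
    p <- length(ids)
    nCase <- sum(y)
    nCtrl <- sum(1 - y)
    cnt <- .mdrCounts(X, y)
    ## one-way: per feature, per-genotype case/control counts (p x 3)
    ca1 <- matrix(unlist(lapply(cnt, function(z) colSums(z$case))), p)
    co1 <- matrix(unlist(lapply(cnt, function(z) colSums(z$ctrl))), p)
    hi1 <- ca1 * nCtrl > co1 * nCase
    ba1 <- 0.5 * (rowSums(ca1 * hi1) / nCase +
                  rowSums(co1 * !hi1) / nCtrl)
    scores <- ba1
    models <- data.frame(locus1 = ids, locus2 = NA_character_, ba = ba1)
    if (maxOrder == 2L && p >= 2L) {
        tp <- matrix(0, p, p)
        tn <- matrix(0, p, p)
        for (g1 in 1:3)
            for (g2 in 1:3) {
                cc <- crossprod(cnt[[g1]]$case, (X == (g2 - 1L)) * 1)
                cn <- crossprod(cnt[[g1]]$ctrl, (X == (g2 - 1L)) * 1)
                hi <- cc * nCtrl > cn * nCase
                tp <- tp + cc * hi
                tn <- tn + cn * !hi
            }
        ba2 <- 0.5 * (tp / nCase + tn / nCtrl)
        ut <- upper.tri(ba2)
        idx <- which(ut, arr.ind = TRUE)
        models <- rbind(models,
            data.frame(locus1 = ids[idx[, 1]], locus2 = ids[idx[, 2]],
                       ba = ba2[ut]))
        best2 <- pmax(apply(ifelse(ut | t(ut), ba2, -Inf), 1, max),
                      -Inf)
        scores <- pmax(ba1, best2)
    }
    models <- models[order(-models$ba), , drop = FALSE]
    rownames(models) <- NULL
    list(ranking = FeatureRanking("mdr", stats::setNames(scores, ids)),
         models = models)
}

#' Materialise a single MDR model
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param loci 1 or 2 feature IDs.
#' @return An \linkS4class{MDRModel} with per-cell counts, high/low labels
#'   and training balanced accuracy.
#' @examples
#' d <- simulateFreqData(freqEffectSpec("1SNP", 0.9), nSnps = 10,
#'                       nCases = 50, nControls = 50, seed = 1)
#' mdrModel(d, "G1")
#' @export
mdrModel <- function(dataset, loci) {
    loci <- as.character(loci)
    if (!length(loci) %in% 1:2 || !all(loci %in% featureIds(dataset)))
        stopf("loci must be 1 or 2 feature IDs of the dataset")
    X <- genotypes(dataset)[, loci, drop = FALSE]
    y <- phenotype(dataset)
    nCase <- sum(y == 1L)
    nCtrl <- sum(y == 0L)
    cells <- if (length(loci) == 1L) as.character(X[, 1])
             else paste(X[, 1], X[, 2], sep = ":")
    lev <- if (length(loci) == 1L) as.character(0:2)
           else as.vector(outer(0:2, 0:2,
                                function(a, b) paste(a, b, sep = ":")))
    ca <- table(factor(cells[y == 1L], levels = lev))
    co <- table(factor(cells[y == 0L], levels = lev))
    hi <- as.numeric(ca) * nCtrl > as.numeric(co) * nCase
    ba <- 0.5 * (sum(ca[hi]) / nCase + sum(co[!hi]) / nCtrl)
    new("MDRModel", loci = loci,
        cellLabels = stats::setNames(ifelse(hi, "high", "low"), lev),
        cellCases = stats::setNames(as.integer(ca), lev),
        cellControls = stats::setNames(as.integer(co), lev),
        balancedAccuracy = ba)
}
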