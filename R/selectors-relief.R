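## Relief-family scorers: MultiSURF* with per-instance distance thresholds
## and a dead band, and the TuRF recursive elimination wrapper.

#' Rank features with MultiSURF*
#'
#' Relief-family attribute weighting with per-instance distance thresholds:
#' for each target instance the mean distance to all other instances defines
#' a threshold, and a dead band of half the standard deviation of those
#' distances on each side separates "near" from "far" neighbours (pairs in
#' the band are ignored). Near neighbours are scored conventionally
#' (miss +diff, hit -diff) and far neighbours with the inverted update
#' (miss -diff, hit +diff); attribute differences are range-normalised
#' (|a - b| / 2 for 0/1/2 genotypes) and final scores are divided by the
#' number of samples. Deterministic: no sampling is involved.
#'
#' @param dataset a \linkS4class{SnpDataset} with at least 3 samples.
#' @return A \linkS4class{FeatureRanking} (method \code{"multisurf_star"}).
#' @examples
#' d <- simulateFreqData(freqEffectSpec("case1_control0", 0.9), nSnps = 20,
#'                       nCases = 100, nControls = 100, seed = 1)
#' utils::head(rankedFeatures(multiSurfStarRank(d)), 2)
#' @export
multiSurfStarRank <- function(dataset) {
    X <- genotypes(dataset)
    if (nrow(X) < 3L) stopf("MultiSURF* needs at least 3 samples")
    y <- as.integer(phenotype(dataset))
    s <- .multisurfStarCpp(X, y)
    FeatureRanking("multisurf_star",
                   stats::setNames(as.numeric(s), featureIds(dataset)))
}

#' TuRF: recursive feature elimination around a base ranker
#'
#' Repeatedly ranks the surviving features with \code{baseRanker} and
#' removes the lowest-scoring \code{floor(dropFraction * current)} features
#' (at least 1) per iteration until no more than \code{minFeatures} remain.
#' The returned ranking orders the survivors by their last-iteration scores
#' and then appends the removed features in reverse order of removal
#' (later-removed ranks higher); removed features are assigned synthetic
#' scores below the surviving minimum that encode that order.
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param baseRanker function(dataset) -> \linkS4class{FeatureRanking}
#'   (default [multiSurfStarRank()]).
#' @param dropFraction fraction of surviving features removed per iteration,
#'   in (0, 1); the study tested 0.01, 0.05, 0.10 (default 0.10).
#' @param minFeatures stop once this many or fewer features survive;
#'   default one tenth of the features (at least 2), enough to cover a
#'   top-10% selection from the final scores.
#' @return A \linkS4class{FeatureRanking} (method
#'   \code{"turf:<base method>"}).
#' @examples
#' d <- simulateFreqData(freqEffectSpec("case1_control0", 0.9), nSnps = 20,
#'                       nCases = 100, nControls = 100, seed = 1)
#' r <- turfRank(d, dropFraction = 0.1)
#' @export
turfRank <- function(dataset, baseRanker = multiSurfStarRank,
                     dropFraction = 0.1,
                     minFeatures = max(2L, floor(length(
                         featureIds(dataset)) / 10))) {
    if (dropFraction <= 0 || dropFraction >= 1)
        stopf("dropFraction must lie in (0, 1)")
    if (minFeatures < 1) stopf("minFeatures must be >= 1")
    ids <- featureIds(dataset)
    surviving <- ids
    removed <- character()           # in removal order (earliest first)
    repeat {
        r <- baseRanker(dataset[surviving, ])
        lastScores <- featureScores(r)
        lastMethod <- selectorMethod(r)
        if (length(surviving) <= minFeatures) break
        nDrop <- max(1L, floor(dropFraction * length(surviving)))
        nDrop <- min(nDrop, length(surviving) - 1L)
        drop <- rev(utils::tail(rankedFeatures(r), nDrop))
        # drop is worst-first within this batch
        removed <- c(removed, drop)
        surviving <- setdiff(surviving, drop)
    }
    base <- min(lastScores)
    # later-removed ranks higher; within the synthetic tail, scores are
    # strictly decreasing so order and scores stay consistent
    synth <- stats::setNames(base - seq_along(removed), rev(removed))
    scores <- c(lastScores, synth)
    FeatureRanking(paste0("turf:", lastMethod), scores[ids])
}
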