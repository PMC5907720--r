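## The collective step: top-k% extraction per ranking and the union
## (and comparison intersection) across heterogeneous methods.

#' Take the top percentage of a ranking
#'
#' k = max(1, round-half-up(p/100 * n)) features from the head of the
#' ranking order (ties are already resolved by the stable index rule).
#' On the study grid (2/3/5/10% of 100 or 500 features) k is always an
#' integer; the half-up rounding and the floor of 1 only matter off-grid.
#'
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param percentage p in (0, 100].
#' @return Character vector of selected feature IDs, best first.
#' @examples
#' r <- FeatureRanking("toy", c(G1 = 3, G2 = 2, G3 = 1))
#' topFraction(r, 34)  # G1
#' @export
topFraction <- function(ranking, percentage) {
    if (percentage <= 0 || percentage > 100)
        stopf("percentage must lie in (0, 100]")
    n <- length(featureScores(ranking))
    k <- max(1L, roundHalfUp(percentage / 100 * n))
    utils::head(rankedFeatures(ranking), k)
}

#' Collective feature selection: union of per-method top sets
#'
#' Applies [topFraction()] to each ranking and forms the union (the
#' collective selection) and, for comparison, the intersection. The
#' percentage applies per method, not to the union size. Which methods
#' selected each feature is recorded as provenance.
#'
#' @param rankings list of \linkS4class{FeatureRanking}s over the
#'   identical feature universe (named by method if the rankings' own
#'   method names are not wanted).
#' @param percentage p in (0, 100].
#' @return A \linkS4class{SelectionResult}.
#' @examples
#' r1 <- FeatureRanking("a", c(G1 = 3, G2 = 2, G3 = 1))
#' r2 <- FeatureRanking("b", c(G1 = 1, G2 = 5, G3 = 2))
#' unionSet(collectiveUnion(list(r1, r2), 34))  # G1, G2
#' @export
collectiveUnion <- function(rankings, percentage) {
    if (!length(rankings)) stopf("at least one ranking is required")
    universe <- names(featureScores(rankings[[1]]))
    for (r in rankings)
        if (!setequal(names(featureScores(r)), universe))
            stopf("rankings cover different feature universes")
    nm <- names(rankings)
    if (is.null(nm))
        nm <- vapply(rankings, selectorMethod, character(1))
    if (anyDuplicated(nm))
        nm <- make.unique(nm)
    per <- stats::setNames(
        lapply(rankings, topFraction, percentage = percentage), nm)
    u <- Reduce(union, per, character())
    u <- universe[universe %in% u]          # stable feature order
    i <- Reduce(intersect, per)
    prov <- lapply(stats::setNames(u, u), function(f)
        nm[vapply(per, function(s) f %in% s, logical(1))])
    new("SelectionResult", percentage = percentage, perMethod = per,
        unionSet = u, intersectionSet = universe[universe %in% i],
        provenance = prov)
}
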