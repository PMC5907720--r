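#' Run a feature-selection method by name
#'
#' Single entry point over all rankers, used by [runBenchmark()] and the
#' command-line script.
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param method one of \code{"mdr"}, \code{"multisurf_star"},
#'   \code{"turf"} (alias \code{"turf:multisurf_star"}), \code{"rf"},
#'   \code{"gbm"}, \code{"lasso"}, \code{"lasso_int"}, \code{"enet"}.
#' @param config settings from [selectorConfig()].
#' @param dropFraction TuRF elimination fraction (default 0.10).
#' @return A \linkS4class{FeatureRanking}.
#' @export
rankFeatures <- function(dataset, method,
                         config = selectorConfig(
                             nFeatures = length(featureIds(dataset))),
                         dropFraction = 0.1) {
    switch(method,
        "mdr" = mdrRank(dataset)$ranking,
        "multisurf_star" = multiSurfStarRank(dataset),
        "turf" = ,
        "turf:multisurf_star" = turfRank(dataset,
            baseRanker = multiSurfStarRank, dropFraction = dropFraction),
        "rf" = rfRank(dataset, config),
        "gbm" = gbmRank(dataset, config),
        "lasso" = ,
        "lasso_int" = ,
        "enet" = penalizedRank(dataset, mode = method, config = config),
        stopf("unknown method '%s'", method))
}
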