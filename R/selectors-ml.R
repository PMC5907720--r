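## Library-delegated tree-ensemble rankers (ranger random forests,
## xgboost gradient boosting) behind the common ranking contract.

#' Selector settings with study presets
#'
#' Bundles the tunable settings of the stochastic and penalized selectors.
#' The \code{"main"} preset follows the study's main-effect configuration
#' (random forest: 1000 trees, 35 variables per split; boosting: 800
#' trees), the \code{"interaction"} preset its interaction configuration
#' (4500 trees and 70 variables per split -- 200 when the dataset has more
#' than 100 SNPs; boosting: 15000 trees). Boosting always uses shrinkage
#' 0.01 and bag fraction 0.5.
#'
#' @param preset \code{"main"} or \code{"interaction"}.
#' @param nFeatures number of SNPs in the target dataset (selects the
#'   interaction-preset variables-per-split value).
#' @param seed RNG seed consumed by the stochastic learners and CV folds.
#' @param rfTrees,rfMtry,rfImportance random-forest overrides
#'   (importance: \code{"permutation"} (default) or \code{"impurity"}).
#' @param gbmTrees,gbmShrinkage,gbmBagFraction,gbmDepth boosting overrides.
#' @param cvFolds,alpha,family penalized-regression settings: number of CV
#'   folds, elastic-net mixing for \code{penalizedRank(mode = "enet")}, and
#'   loss (\code{"binomial"} logistic deviance, default, or
#'   \code{"gaussian"} squared error).
#' @return A named list of settings.
#' @export
selectorConfig <- function(preset = c("interaction", "main"),
                           nFeatures = 100, seed = 1,
                           rfTrees = NULL, rfMtry = NULL,
                           rfImportance = c("permutation", "impurity"),
                           gbmTrees = NULL, gbmShrinkage = 0.01,
                           gbmBagFraction = 0.5, gbmDepth = 2,
                           cvFolds = 5, alpha = 0.5,
                           family = c("binomial", "gaussian")) {
    preset <- match.arg(preset)
    rfImportance <- match.arg(rfImportance)
    family <- match.arg(family)
    if (is.null(rfTrees))
        rfTrees <- if (preset == "main") 1000 else 4500
    if (is.null(rfMtry))
        rfMtry <- if (preset == "main") 35
                  else if (nFeatures > 100) 200 else 70
    if (is.null(gbmTrees))
        gbmTrees <- if (preset == "main") 800 else 15000
    cfg <- list(preset = preset, seed = as.integer(seed),
                rfTrees = as.integer(rfTrees),
                rfMtry = as.integer(rfMtry), rfImportance = rfImportance,
                gbmTrees = as.integer(gbmTrees),
                gbmShrinkage = gbmShrinkage,
                gbmBagFraction = gbmBagFraction,
                gbmDepth = as.integer(gbmDepth),
                cvFolds = as.integer(cvFolds), alpha = alpha,
                family = family)
    stopifnot(cfg$rfTrees > 0, cfg$gbmTrees > 0, cfg$rfMtry > 0,
              cfg$gbmShrinkage > 0, cfg$gbmBagFraction > 0,
              cfg$gbmBagFraction <= 1, cfg$cvFolds > 1,
              cfg$alpha >= 0, cfg$alpha <= 1)
    cfg
}

#' Rank features by random-forest variable importance
#'
#' Fits a ranger classification forest and scores every feature by its
#' variable importance (permutation importance by default). Deterministic
#' given \code{config$seed}.
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param config settings from [selectorConfig()].
#' @return A \linkS4class{FeatureRanking} (method \code{"rf"}).
#' @export
rfRank <- function(dataset, config = selectorConfig(
                       nFeatures = length(featureIds(dataset)))) {
    X <- genotypes(dataset)
    y <- factor(phenotype(dataset), levels = c(0, 1))
    fit <- ranger::ranger(
        x = X, y = y, num.trees = config$rfTrees,
        mtry = min(config$rfMtry, ncol(X)),
        importance = config$rfImportance, seed = config$seed,
        num.threads = 1L)
    imp <- fit$variable.importance[featureIds(dataset)]
    FeatureRanking("rf", imp)
}

#' Rank features by gradient-boosting importance
#'
#' Fits a stochastic gradient-boosted tree ensemble (xgboost; logistic
#' loss, shrinkage 0.01, bag fraction 0.5 by default) and scores every
#' feature by its total loss-reduction (gain) importance; features never
#' used by a split score 0. Deterministic given \code{config$seed}.
#'
#' @inheritParams rfRank
#' @return A \linkS4class{FeatureRanking} (method \code{"gbm"}).
#' @export
gbmRank <- function(dataset, config = selectorConfig(
                        nFeatures = length(featureIds(dataset)))) {
    X <- genotypes(dataset)
    storage.mode(X) <- "double"
    y <- as.numeric(phenotype(dataset))
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    params <- list(objective = "binary:logistic",
                   eta = config$gbmShrinkage,
                   subsample = config$gbmBagFraction,
                   max_depth = config$gbmDepth,
                   lambda = 0, alpha = 0,
                   tree_method = "hist", nthread = 1,
                   seed = config$seed)
    fit <- withSeed(config$seed,
        xgboost::xgb.train(params = params, data = dtrain,
                           nrounds = config$gbmTrees, verbose = 0))
    imp <- xgboost::xgb.importance(model = fit)
    scores <- stats::setNames(numeric(length(featureIds(dataset))),
                              featureIds(dataset))
    scores[imp$Feature] <- imp$Gain
    FeatureRanking("gbm", scores)
}
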