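## Penalized logistic/linear regression rankers (glmnet) with a bespoke
## exhaustive pairwise-interaction design expansion and score attribution
## from interaction coefficients back to the member SNPs.

#' Build the main + exhaustive pairwise-interaction design
#'
#' Appends product columns x_j * x_k for all j < k to the p main-effect
#' columns (so p + p(p-1)/2 columns in total) and standardizes every column
#' to zero mean, unit variance. Columns that are constant (zero variance,
#' e.g. a product of near-monomorphic SNPs) are dropped with a message and
#' recorded, and the attribution map is updated accordingly.
#'
#' @param genotypes samples-by-SNPs matrix (from [genotypes()]).
#' @return List with \code{x} (standardized design), \code{map}
#'   (data.frame: column name, type \code{"main"}/\code{"interaction"},
#'   member feature IDs \code{f1}, \code{f2}) and \code{dropped}
#'   (character vector of dropped column names).
#' @examples
#' d <- simulateFreqData(freqEffectSpec("2SNP", 0.5), nSnps = 5,
#'                       nCases = 30, nControls = 30, seed = 1)
#' dim(buildInteractionDesign(genotypes(d))$x)  # 60 x 15
#' @export
buildInteractionDesign <- function(genotypes) {
    X <- as.matrix(genotypes)
    p <- ncol(X)
    if (p < 2L) stopf("interaction design needs at least 2 SNPs")
    ids <- colnames(X)
    if (is.null(ids)) ids <- paste0("G", seq_len(p))
    idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    Z <- X[, idx[, 1], drop = FALSE] * X[, idx[, 2], drop = FALSE]
    intNames <- paste(ids[idx[, 1]], ids[idx[, 2]], sep = ":")
    colnames(Z) <- intNames
    colnames(X) <- ids
    full <- cbind(X, Z)
    map <- data.frame(
        column = c(ids, intNames),
        type = rep(c("main", "interaction"), c(p, nrow(idx))),
        f1 = c(ids, ids[idx[, 1]]),
        f2 = c(rep(NA_character_, p), ids[idx[, 2]]),
        stringsAsFactors = FALSE)
    sds <- apply(full, 2, stats::sd)
    dropped <- colnames(full)[sds == 0]
    if (length(dropped)) {
        message("dropping ", length(dropped),
                " constant design column(s): ",
                paste(utils::head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else "")
        full <- full[, sds > 0, drop = FALSE]
        map <- map[map$column %in% colnames(full), , drop = FALSE]
    }
    x <- scale(full)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    list(x = x, map = map, dropped = dropped)
}

# seeded stratified fold assignment (each class spread across folds)
.stratifiedFolds <- function(y, k, seed) {
    foldid <- integer(length(y))
    withSeed(seed, {
        for (cl in unique(y)) {
            i <- which(y == cl)
            foldid[i] <- sample(rep_len(seq_len(k), length(i)))
        }
    })
    if (any(table(factor(foldid, levels = seq_len(k)),
              factor(y)) == 0))
        stopf(paste0("a CV fold received a single class; use a different ",
                     "seed or fewer folds"))
    foldid
}

#' Rank features by penalized regression
#'
#' Fits a glmnet regularization path and selects the penalty lambda
#' minimizing 5-fold stratified cross-validated loss (logistic deviance by
#' default; squared error with \code{config$family = "gaussian"}). Feature
#' scores are absolute coefficients at the chosen lambda; under
#' \code{"lasso_int"} the design from [buildInteractionDesign()] is used
#' and each feature is scored by the largest absolute coefficient among
#' its main term and all interaction terms containing it, so either member
#' of a selected interaction is promoted.
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param mode \code{"lasso"} (L1, main effects), \code{"lasso_int"}
#'   (L1, main + exhaustive pairwise interactions) or \code{"enet"}
#'   (elastic net, mixing \code{config$alpha} = 0.5 by default, main
#'   effects; set \code{interactions = TRUE} to expand).
#' @param config settings from [selectorConfig()].
#' @param interactions override the design choice implied by \code{mode}.
#' @return A \linkS4class{FeatureRanking} (method = \code{mode}).
#' @export
penalizedRank <- function(dataset, mode = c("lasso", "lasso_int", "enet"),
                          config = selectorConfig(
                              nFeatures = length(featureIds(dataset))),
                          interactions = NULL) {
    mode <- match.arg(mode)
    if (is.null(interactions)) interactions <- mode == "lasso_int"
    alpha <- if (mode == "enet") config$alpha else 1
    ids <- featureIds(dataset)
    X <- genotypes(dataset)
    y <- as.numeric(phenotype(dataset))
    if (interactions) {
        des <- buildInteractionDesign(X)
    } else {
        sds <- apply(X, 2, stats::sd)
        keep <- sds > 0
        des <- list(x = scale(X[, keep, drop = FALSE]),
                    map = data.frame(column = ids[keep], type = "main",
                                     f1 = ids[keep], f2 = NA_character_,
                                     stringsAsFactors = FALSE),
                    dropped = ids[!keep])
    }
    foldid <- .stratifiedFolds(y, config$cvFolds, config$seed)
    cv <- glmnet::cv.glmnet(des$x, y, family = config$family,
                            alpha = alpha, foldid = foldid,
                            standardize = FALSE)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    names(beta) <- colnames(des$x)
    scores <- stats::setNames(numeric(length(ids)), ids)
    ab <- abs(beta)
    m <- des$map
    mainRows <- m$type == "main"
    scores[m$f1[mainRows]] <- pmax(scores[m$f1[mainRows]],
                                   ab[m$column[mainRows]])
    intRows <- which(m$type == "interaction")
    for (r in intRows) {
        v <- ab[m$column[r]]
        if (v > scores[m$f1[r]]) scores[m$f1[r]] <- v
        if (v > scores[m$f2[r]]) scores[m$f2[r]] <- v
    }
    FeatureRanking(mode, scores)
}
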