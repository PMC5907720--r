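#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' TruthManifest: the causal loci of a simulated dataset
#'
#' Records which features carry simulated signal, how they are organised
#' (singleton main effects or interacting pairs) and in which class each unit
#' is enriched.
#'
#' @slot causalIds character vector of causal feature IDs (the flattened
#'   union of \code{effectStructure}).
#' @slot modelName scalar character naming the generating model
#'   (e.g. \code{"2SNP"}, \code{"case1_control1"}, \code{"gametes_easy_h0.2"}).
#' @slot effectStructure list of units; each unit is a list with elements
#'   \code{ids} (1 or 2 feature IDs) and \code{enriched}
#'   (\code{"case"} or \code{"control"}).
#' @exportClass TruthManifest
setClass("TruthManifest",
    representation(causalIds = "character",
                   modelName = "character",
                   effectStructure = "list"))

setValidity("TruthManifest", function(object) {
    msg <- NULL
    for (u in object@effectStructure) {
        if (!is.list(u) || is.null(u$ids) || is.null(u$enriched))
            return("each effect unit needs 'ids' and 'enriched'")
        if (!length(u$ids) %in% c(1L, 2L))
            msg <- c(msg, "effect units must have 1 or 2 loci")
        if (!u$enriched %in% c("case", "control"))
            msg <- c(msg, "unit 'enriched' must be 'case' or 'control'")
    }
    flat <- unique(unlist(lapply(object@effectStructure, `[[`, "ids")))
    if (!setequal(object@causalIds, flat))
        msg <- c(msg, "causalIds must equal the union of effectStructure ids")
    if (anyDuplicated(object@causalIds))
        msg <- c(msg, "causalIds must be unique")
    if (length(object@modelName) != 1L)
        msg <- c(msg, "modelName must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' SnpDataset: case/control genotypes as a SummarizedExperiment
#'
#' Rows are SNPs (additively coded 0/1/2 counts of the minor allele), columns
#' are samples, following the features-by-samples convention. Case/control
#' status lives in \code{colData(x)$status} (0 = control, 1 = case). For
#' simulated data the truth manifest and provenance (generator, seed,
#' replicate) are carried in \code{metadata(x)}.
#'
#' @seealso [SnpDataset()], [genotypes()], [phenotype()], [truthManifest()]
#' @exportClass SnpDataset
setClass("SnpDataset", contains = "SummarizedExperiment")

setValidity("SnpDataset", function(object) {
    msg <- NULL
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        return("assay 'genotype' is required")
    g <- SummarizedExperiment::assay(object, "genotype")
    if (anyNA(g))
        msg <- c(msg, "missing genotypes are not supported")
    else if (!all(g %in% c(0L, 1L, 2L)))
        msg <- c(msg, "genotype values must all be 0, 1 or 2")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature IDs (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample IDs (colnames) must be present and unique")
    st <- object$status
    if (is.null(st) || !all(st %in% c(0L, 1L)))
        msg <- c(msg, "colData$status must be 0 (control) / 1 (case)")
    else if (ncol(object) > 0L && (all(st == 0L) || all(st == 1L)))
        msg <- c(msg, "at least one case and one control are required")
    tr <- S4Vectors::metadata(object)$truth
    if (!is.null(tr)) {
        if (!is(tr, "TruthManifest"))
            msg <- c(msg, "metadata$truth must be a TruthManifest")
        else if (!all(tr@causalIds %in% rownames(object)))
            msg <- c(msg, "truth causalIds must be a subset of feature IDs")
    }
    if (is.null(msg)) TRUE else msg
})

#' FeatureRanking: per-feature scores and a total order from one selector
#'
#' @slot method scalar character, the selector that produced the ranking.
#' @slot scores named numeric vector in the dataset's feature (column) order;
#'   higher means more important.
#' @slot order character permutation of the feature IDs, sorted by
#'   descending score with ties broken by ascending feature index (stable).
#' @exportClass FeatureRanking
setClass("FeatureRanking",
    representation(method = "character",
                   scores = "numeric",
                   order = "character"))

setValidity("FeatureRanking", function(object) {
    msg <- NULL
    ids <- names(object@scores)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "scores must be uniquely named by feature ID")
    if (!setequal(object@order, ids) ||
        length(object@order) != length(ids))
        msg <- c(msg, "order must be a permutation of the scored features")
    else {
        s <- object@scores[object@order]
        if (is.unsorted(rev(s)))  # descending
            msg <- c(msg, "order must sort scores in descending order")
    }
    if (anyNA(object@scores)) msg <- c(msg, "scores must be finite")
    if (is.null(msg)) TRUE else msg
})

#' SelectionResult: per-method top-k sets and their union/intersection
#'
#' @slot percentage percentage of features taken from each ranking (0, 100].
#' @slot perMethod named list, method -> character vector of selected IDs
#'   (in ranking order).
#' @slot unionSet union of the per-method sets (the collective selection).
#' @slot intersectionSet intersection of the per-method sets.
#' @slot provenance named list, feature ID -> character vector of the
#'   methods that selected it.
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(percentage = "numeric",
                   perMethod = "list",
                   unionSet = "character",
                   intersectionSet = "character",
                   provenance = "list"))

setValidity("SelectionResult", function(object) {
    msg <- NULL
    if (length(object@percentage) != 1L || object@percentage <= 0 ||
        object@percentage > 100)
        msg <- c(msg, "percentage must be a scalar in (0, 100]")
    u <- Reduce(union, object@perMethod, character())
    i <- Reduce(intersect, object@perMethod)
    if (!setequal(u, object@unionSet))
        msg <- c(msg, "unionSet must equal the union of per-method sets")
    if (!setequal(i, object@intersectionSet))
        msg <- c(msg, "intersectionSet must equal the intersection")
    if (is.null(msg)) TRUE else msg
})

#' PenetranceModel: a two-locus penetrance table with its population summary
#'
#' Penetrance f(g1, g2) is the probability of disease given the genotype
#' pair. Under Hardy-Weinberg genotype weights at the stored MAF the table
#' determines the prevalence K, the (penetrance-based) heritability h2, and
#' an ease-of-detection score; pure-strict models additionally have all
#' single-locus marginal penetrances equal to K.
#'
#' @slot f 3x3 numeric matrix of penetrances in [0, 1]; rows index locus-1
#'   genotypes 0/1/2, columns locus-2 genotypes.
#' @slot maf minor allele frequency shared by both loci.
#' @slot prevalence K, the HWE-weighted mean penetrance.
#' @slot h2 heritability: HWE-weighted variance of f about K over K(1 - K).
#' @slot edm ease-of-detection score (analytic Bayes-optimal two-locus
#'   balanced accuracy; see [edmProxy()]).
#' @slot kind \code{"pure_pair"} or \code{"combined"}.
#' @exportClass PenetranceModel
setClass("PenetranceModel",
    representation(f = "matrix", maf = "numeric", prevalence = "numeric",
                   h2 = "numeric", edm = "numeric", kind = "character"))

setValidity("PenetranceModel", function(object) {
    msg <- NULL
    if (!all(dim(object@f) == c(3L, 3L)))
        msg <- c(msg, "penetrance table must be 3x3")
    if (any(object@f < -1e-12) || any(object@f > 1 + 1e-12))
        msg <- c(msg, "penetrances must lie in [0, 1]")
    if (object@prevalence <= 0 || object@prevalence >= 1)
        msg <- c(msg, "prevalence must lie in (0, 1)")
    w <- hweProbs(object@maf)
    K <- as.numeric(t(w) %*% object@f %*% w)
    if (abs(K - object@prevalence) > 1e-9)
        msg <- c(msg, "stored prevalence does not match the table")
    h2 <- as.numeric(t(w) %*% (object@f - K)^2 %*% w) / (K * (1 - K))
    if (abs(h2 - object@h2) > 1e-9)
        msg <- c(msg, "stored h2 does not match the table")
    if (!object@kind %in% c("pure_pair", "combined"))
        msg <- c(msg, "kind must be 'pure_pair' or 'combined'")
    if (is.null(msg)) TRUE else msg
})

#' CombinedModel: pure two-locus epistasis plus an additive third-locus
#' main effect
#'
#' The 27-cell penetrance is
#' f(g1, g2, g3) = K + ce * (f_epi(g1, g2) - K) + cm * dMain(g3),
#' with both deviation components zero-mean under HWE weights, so the total
#' heritability decomposes as (ce^2 V_epi + cm^2 V_main) / (K (1 - K)).
#'
#' @slot epi the pure-pair [PenetranceModel-class] providing the epistatic
#'   deviations (before rescaling by \code{ce}).
#' @slot mainDev length-3 zero-HWE-mean deviation for the third locus
#'   (unit direction; scaled by \code{cm}).
#' @slot ce,cm component scalings.
#' @slot prevalence K of the combined model.
#' @slot h2Total total heritability of the 27-cell table.
#' @slot table 3x3x3 array of combined penetrances (g1, g2, g3).
#' @exportClass CombinedModel
setClass("CombinedModel",
    representation(epi = "PenetranceModel", mainDev = "numeric",
                   ce = "numeric", cm = "numeric",
                   prevalence = "numeric", h2Total = "numeric",
                   table = "array"))

setValidity("CombinedModel", function(object) {
    msg <- NULL
    if (!all(dim(object@table) == c(3L, 3L, 3L)))
        msg <- c(msg, "combined table must be 3x3x3")
    if (any(object@table < -1e-12) || any(object@table > 1 + 1e-12))
        msg <- c(msg, "combined penetrances must lie in [0, 1]")
    w <- hweProbs(object@epi@maf)
    if (abs(sum(w * object@mainDev)) > 1e-9)
        msg <- c(msg, "mainDev must have zero HWE mean")
    if (is.null(msg)) TRUE else msg
})

#' FreqEffectSpec: frequency-shift simulation design (experiment-1 style)
#'
#' Describes the causal units of a balanced case/control dataset in which
#' causal SNPs (singletons or pairs) have different (joint) genotype
#' frequencies in cases versus controls; see [freqEffectSpec()].
#'
#' @slot modelName one of \code{"1SNP"}..\code{"4SNP"},
#'   \code{"case1_control0"}, \code{"case1_control1"},
#'   \code{"case2_control0"}, \code{"case2_control2"}.
#' @slot signal mixing weight s in [0, 1): strength of the frequency shift.
#' @slot maf baseline minor allele frequency (default 0.4).
#' @slot units list of causal units; each has \code{ids}, \code{enriched},
#'   \code{caseTable} and \code{controlTable} (length-3 vector for
#'   singletons, 3x3 joint matrix for pairs; each sums to 1).
#' @exportClass FreqEffectSpec
setClass("FreqEffectSpec",
    representation(modelName = "character", signal = "numeric",
                   maf = "numeric", units = "list"))

setValidity("FreqEffectSpec", function(object) {
    msg <- NULL
    if (object@signal < 0 || object@signal >= 1)
        msg <- c(msg, "signal must lie in [0, 1)")
    if (object@maf <= 0 || object@maf > 0.5)
        msg <- c(msg, "maf must lie in (0, 0.5]")
    for (u in object@units) {
        for (tab in list(u$caseTable, u$controlTable)) {
            if (any(tab < 0) || abs(sum(tab) - 1) > 1e-12)
                msg <- c(msg,
                    "frequency tables must be non-negative and sum to 1")
            n <- if (length(u$ids) == 1L) 3L else 9L
            if (length(tab) != n)
                msg <- c(msg, "table dimension must match unit arity")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' MDRModel: one exhaustive-search MDR model
#'
#' A one- or two-locus multifactor dimensionality reduction model: each
#' genotype cell is labelled high-risk when its case:control ratio strictly
#' exceeds the dataset-wide ratio (empty cells and exact ties are low-risk),
#' and the model is scored by training balanced accuracy.
#'
#' @slot loci 1 or 2 feature IDs.
#' @slot cellLabels named character vector over genotype cells
#'   (\code{"0"},\code{"1"},\code{"2"} or \code{"0:0"}..\code{"2:2"}),
#'   values \code{"high"}/\code{"low"}.
#' @slot cellCases,cellControls named integer counts per cell.
#' @slot balancedAccuracy training balanced accuracy (TPR + TNR) / 2.
#' @exportClass MDRModel
setClass("MDRModel",
    representation(loci = "character", cellLabels = "character",
                   cellCases = "integer", cellControls = "integer",
                   balancedAccuracy = "numeric"))
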