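#' Construct a SnpDataset
#'
#' Builds the package's central data object from a samples-by-SNPs genotype
#' matrix and a binary phenotype. Internally the object is a
#' \linkS4class{SummarizedExperiment} with SNPs as rows and samples as
#' columns; [genotypes()] returns the samples-by-SNPs orientation that the
#' selectors consume.
#'
#' @param genotypes integer matrix, samples in rows and SNPs in columns,
#'   every entry 0, 1 or 2 (additive minor-allele count). Column/row names
#'   are used as feature/sample IDs when present.
#' @param status integer (or coercible) vector of 0 = control / 1 = case,
#'   one per sample.
#' @param featureIds,sampleIds optional explicit IDs overriding dimnames;
#'   defaults are \code{G1..Gp} and \code{S1..Sn}.
#' @param truth optional \linkS4class{TruthManifest}.
#' @param generator provenance tag (\code{"freq"}, \code{"gametes"} or
#'   \code{NA} for data read from files).
#' @param seed,replicate provenance of simulated datasets.
#' @return A \linkS4class{SnpDataset}.
#' @examples
#' g <- matrix(c(0L,1L,2L,0L, 1L,1L,0L,2L), nrow = 4)
#' d <- SnpDataset(g, status = c(0, 0, 1, 1))
#' genotypes(d)
#' phenotype(d)
#' @export
SnpDataset <- function(genotypes, status, featureIds = NULL,
                       sampleIds = NULL, truth = NULL,
                       generator = NA_character_, seed = NA_integer_,
                       replicate = NA_integer_) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    if (is.null(featureIds))
        featureIds <- colnames(genotypes)
    if (is.null(featureIds))
        featureIds <- paste0("G", seq_len(ncol(genotypes)))
    if (is.null(sampleIds))
        sampleIds <- rownames(genotypes)
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(nrow(genotypes)))
    status <- as.integer(status)
    if (length(status) != nrow(genotypes))
        stopf("phenotype length (%d) must equal the number of samples (%d)",
              length(status), nrow(genotypes))
    a <- t(genotypes)
    dimnames(a) <- list(featureIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(genotype = a),
        colData = S4Vectors::DataFrame(status = status, row.names = sampleIds))
    obj <- new("SnpDataset", se)
    S4Vectors::metadata(obj) <- list(truth = truth, generator = generator,
                                     seed = seed, replicate = replicate)
    validObject(obj)
    obj
}

#' @describeIn SnpDataset samples-by-SNPs integer genotype matrix.
#' @param x a SnpDataset.
#' @export
setMethod("genotypes", "SnpDataset", function(x) {
    t(SummarizedExperiment::assay(x, "genotype"))
})

#' @describeIn SnpDataset named integer 0/1 phenotype (0 control, 1 case).
#' @export
setMethod("phenotype", "SnpDataset", function(x) {
    stats::setNames(x$status, colnames(x))
})

#' @describeIn SnpDataset feature (SNP) identifiers.
#' @export
setMethod("featureIds", "SnpDataset", function(x) rownames(x))

#' @describeIn SnpDataset sample identifiers.
#' @export
setMethod("sampleIds", "SnpDataset", function(x) colnames(x))

#' @describeIn SnpDataset the attached \linkS4class{TruthManifest}
#'   (or NULL).
#' @export
setMethod("truthManifest", "SnpDataset", function(x)
    S4Vectors::metadata(x)$truth)

#' @describeIn SnpDataset attach (or remove) a truth manifest.
#' @param value a TruthManifest or NULL.
#' @export
setReplaceMethod("truthManifest", "SnpDataset", function(x, value) {
    md <- S4Vectors::metadata(x)
    md$truth <- value
    S4Vectors::metadata(x) <- md
    validObject(x)
    x
})

#' @describeIn SnpDataset causal feature IDs of the attached truth
#'   (empty if none).
#' @export
setMethod("causalIds", "SnpDataset", function(x) {
    tr <- truthManifest(x)
    if (is.null(tr)) character() else tr@causalIds
})

setMethod("show", "SnpDataset", function(object) {
    st <- object$status
    cat(sprintf("SnpDataset: %d SNPs x %d samples (%d cases / %d controls)\n",
                nrow(object), ncol(object), sum(st == 1L), sum(st == 0L)))
    md <- S4Vectors::metadata(object)
    if (!is.na(md$generator %||% NA))
        cat(sprintf("  generator: %s (seed %s, replicate %s)\n",
                    md$generator, md$seed, md$replicate))
    tr <- md$truth
    if (!is.null(tr))
        cat(sprintf("  truth: model '%s', %d causal SNP(s): %s\n",
                    tr@modelName, length(tr@causalIds),
                    paste(tr@causalIds, collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- TruthManifest ----

#' Construct a TruthManifest
#'
#' @param effectStructure list of units, each \code{list(ids =, enriched =)}
#'   with 1 or 2 feature IDs and enrichment class \code{"case"} or
#'   \code{"control"}.
#' @param modelName name of the generating model.
#' @return A \linkS4class{TruthManifest}.
#' @examples
#' TruthManifest(list(list(ids = c("G1", "G2"), enriched = "case")), "pair")
#' @export
TruthManifest <- function(effectStructure, modelName) {
    new("TruthManifest",
        causalIds = unique(unlist(lapply(effectStructure, `[[`, "ids"))),
        modelName = as.character(modelName),
        effectStructure = effectStructure)
}

#' @describeIn TruthManifest causal feature IDs.
#' @param x a TruthManifest.
#' @export
setMethod("causalIds", "TruthManifest", function(x) x@causalIds)

#' @describeIn TruthManifest list of causal units.
#' @export
setMethod("effectStructure", "TruthManifest", function(x)
    x@effectStructure)

setMethod("show", "TruthManifest", function(object) {
    cat(sprintf("TruthManifest '%s': %d causal feature(s)\n",
                object@modelName, length(object@causalIds)))
    for (u in object@effectStructure)
        cat(sprintf("  %s  [%s-enriched]\n",
                    paste(u$ids, collapse = " <-> "), u$enriched))
})

## ---- FeatureRanking ----

#' Build a FeatureRanking from raw scores
#'
#' Orders features by descending score; ties are broken by ascending input
#' (feature-index) position, the package-wide stable tie rule.
#'
#' @param method name of the selector.
#' @param scores numeric vector of scores, named by feature ID in the
#'   dataset's column order.
#' @return A \linkS4class{FeatureRanking}.
#' @examples
#' FeatureRanking("toy", c(G1 = 0.2, G2 = 0.9, G3 = 0.2))
#' @export
FeatureRanking <- function(method, scores) {
    if (is.null(names(scores)))
        stopf("scores must be named by feature ID")
    ord <- names(scores)[order(-scores, seq_along(scores))]
    new("FeatureRanking", method = as.character(method),
        scores = scores, order = ord)
}

#' @describeIn FeatureRanking named score vector (input feature order).
#' @param x a FeatureRanking.
#' @export
setMethod("featureScores", "FeatureRanking", function(x) x@scores)

#' @describeIn FeatureRanking feature IDs best-first.
#' @export
setMethod("rankedFeatures", "FeatureRanking", function(x) x@order)

#' @describeIn FeatureRanking the producing selector's name.
#' @export
setMethod("selectorMethod", "FeatureRanking", function(x) x@method)

setMethod("show", "FeatureRanking", function(object) {
    n <- length(object@scores)
    top <- utils::head(object@order, 5L)
    cat(sprintf("FeatureRanking (%s): %d features\n", object@method, n))
    cat("  top:", paste(sprintf("%s (%.4g)", top, object@scores[top]),
                        collapse = ", "), "\n")
})

## ---- SelectionResult ----

#' @describeIn SelectionResult the collective (union) selection.
#' @param x a SelectionResult.
#' @export
setMethod("unionSet", "SelectionResult", function(x) x@unionSet)

#' @describeIn SelectionResult features selected by every method.
#' @export
setMethod("intersectionSet", "SelectionResult", function(x)
    x@intersectionSet)

#' @describeIn SelectionResult named list of per-method top sets.
#' @export
setMethod("perMethodSets", "SelectionResult", function(x) x@perMethod)

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf(
        "SelectionResult: top %g%% from %d method(s); |union| = %d, |intersection| = %d\n",
        object@percentage, length(object@perMethod),
        length(object@unionSet), length(object@intersectionSet)))
    for (m in names(object@perMethod))
        cat(sprintf("  %-18s %d feature(s)\n", m,
                    length(object@perMethod[[m]])))
})

## ---- PenetranceModel ----

#' @describeIn PenetranceModel the 3x3 (or, for CombinedModel, 3x3x3)
#'   penetrance table.
#' @param x a PenetranceModel.
#' @export
setMethod("penetranceTable", "PenetranceModel", function(x) x@f)

#' @describeIn PenetranceModel prevalence K.
#' @export
setMethod("prevalence", "PenetranceModel", function(x) x@prevalence)

#' @describeIn PenetranceModel heritability h2.
#' @export
setMethod("heritability", "PenetranceModel", function(x) x@h2)

setMethod("show", "PenetranceModel", function(object) {
    cat(sprintf(
        "PenetranceModel (%s): MAF %.3g, K = %.4g, h2 = %.4g, EDM = %.4g\n",
        object@kind, object@maf, object@prevalence, object@h2, object@edm))
    print(round(object@f, 4))
})

#' @describeIn CombinedModel the 3x3x3 combined penetrance array.
#' @param x a CombinedModel.
#' @export
setMethod("penetranceTable", "CombinedModel", function(x) x@table)

#' @describeIn CombinedModel prevalence K of the combined model.
#' @export
setMethod("prevalence", "CombinedModel", function(x) x@prevalence)

#' @describeIn CombinedModel total heritability of the 27-cell table.
#' @export
setMethod("heritability", "CombinedModel", function(x) x@h2Total)

setMethod("show", "CombinedModel", function(object) {
    cat(sprintf(
        "CombinedModel: K = %.4g, total h2 = %.4g (ce = %.4g, cm = %.4g)\n",
        object@prevalence, object@h2Total, object@ce, object@cm))
})

setMethod("show", "MDRModel", function(object) {
    cat(sprintf("MDRModel [%s]: balanced accuracy %.4f\n",
                paste(object@loci, collapse = " x "),
                object@balancedAccuracy))
    hi <- names(object@cellLabels)[object@cellLabels == "high"]
    cat("  high-risk cells:",
        if (length(hi)) paste(hi, collapse = ", ") else "(none)", "\n")
})
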