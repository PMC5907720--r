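## Readers/writers for genotype datasets, truth manifests and rankings.
## Two dialects are supported:
##   gametes_tsv - tab-delimited, header of feature IDs then a literal
##                 "Class" column; one row per sample; genotypes 0/1/2.
##   plink_raw   - whitespace-delimited with leading FID IID PAT MAT SEX
##                 PHENOTYPE columns; PHENOTYPE 1/2 mapped to 0/1 status;
##                 remaining columns are 0/1/2 allele dosages.
## Missing genotypes are rejected: the simulators never emit them and every
## selector's arithmetic assumes complete 0/1/2 data.

.checkGenotypeCells <- function(m, path) {
    bad <- which(!(m %in% c(0, 1, 2)) | is.na(m))
    if (length(bad)) {
        i <- ((bad[1] - 1) %% nrow(m)) + 1
        j <- ((bad[1] - 1) %/% nrow(m)) + 1
        stopf(paste0("invalid genotype value '%s' at sample row %d, ",
                     "feature column %d ('%s') in %s"),
              as.character(m[bad[1]]), i, j, colnames(m)[j], path)
    }
}

#' Read a case/control genotype dataset
#'
#' @param path file to read.
#' @param dialect \code{"gametes_tsv"} or \code{"plink_raw"}.
#' @return A \linkS4class{SnpDataset} without a truth manifest (attach one
#'   read with [readTruthManifest()] via \code{truthManifest(x) <- ...}).
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, dialect = c("gametes_tsv", "plink_raw")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stopf("file not found: %s", path)
    df <- utils::read.table(path, header = TRUE, sep = if (dialect ==
        "gametes_tsv") "\t" else "", check.names = FALSE,
        stringsAsFactors = FALSE)
    if (anyDuplicated(colnames(df)))
        stopf("duplicate feature IDs in %s", path)
    if (dialect == "gametes_tsv") {
        if (!"Class" %in% colnames(df))
            stopf("gametes_tsv file %s has no 'Class' column", path)
        status <- df[["Class"]]
        if (!all(status %in% c(0, 1)))
            stopf("Class column of %s must be 0/1", path)
        g <- as.matrix(df[, -which(colnames(df) == "Class"),
                          drop = FALSE])
        sampleIds <- paste0("S", seq_len(nrow(g)))
    } else {
        lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
        if (!all(lead %in% colnames(df)))
            stopf("plink_raw file %s lacks the %s columns", path,
                  paste(lead, collapse = "/"))
        if (!all(df$PHENOTYPE %in% c(1, 2)))
            stopf("PHENOTYPE column of %s must be 1 (control) / 2 (case)",
                  path)
        status <- df$PHENOTYPE - 1L
        g <- as.matrix(df[, !(colnames(df) %in% lead), drop = FALSE])
        sampleIds <- as.character(df$IID)
    }
    if (anyDuplicated(colnames(g)))
        stopf("duplicate feature IDs in %s", path)
    if (anyDuplicated(sampleIds))
        stopf("duplicate sample IDs in %s", path)
    .checkGenotypeCells(g, path)
    storage.mode(g) <- "integer"
    SnpDataset(g, status = as.integer(status), featureIds = colnames(g),
               sampleIds = sampleIds)
}

#' Write a genotype dataset (and its truth manifest sidecar)
#'
#' When the dataset carries a truth manifest it is written alongside the
#' genotype file as \code{<path>.truth.yaml}.
#'
#' @param dataset a \linkS4class{SnpDataset}.
#' @param path output file.
#' @param dialect \code{"gametes_tsv"} or \code{"plink_raw"}.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypes <- function(dataset, path,
                           dialect = c("gametes_tsv", "plink_raw")) {
    dialect <- match.arg(dialect)
    validObject(dataset)
    g <- genotypes(dataset)
    st <- phenotype(dataset)
    if (dialect == "gametes_tsv") {
        df <- as.data.frame(g, check.names = FALSE)
        df$Class <- as.integer(st)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        df <- data.frame(FID = sampleIds(dataset), IID = sampleIds(dataset),
                         PAT = 0L, MAT = 0L, SEX = 0L,
                         PHENOTYPE = as.integer(st) + 1L,
                         check.names = FALSE)
        df <- cbind(df, as.data.frame(g, check.names = FALSE))
        utils::write.table(df, path, sep = " ", quote = FALSE,
                           row.names = FALSE)
    }
    tr <- truthManifest(dataset)
    if (!is.null(tr)) {
        md <- S4Vectors::metadata(dataset)
        writeTruthManifest(tr, paste0(path, ".truth.yaml"),
                           seed = md$seed, replicate = md$replicate)
    }
    invisible(path)
}

#' Write a truth manifest as structured text (YAML)
#'
#' @param truth a \linkS4class{TruthManifest}.
#' @param path output file.
#' @param seed,replicate optional provenance recorded in the file.
#' @return Invisibly, \code{path}.
#' @export
writeTruthManifest <- function(truth, path, seed = NA, replicate = NA) {
    x <- list(model_name = truth@modelName,
              causal_ids = as.list(truth@causalIds),
              effect_structure = lapply(truth@effectStructure, function(u)
                  list(ids = as.list(u$ids), enriched = u$enriched)),
              seed = if (is.na(seed)) NULL else as.integer(seed),
              replicate = if (is.na(replicate)) NULL else
                  as.integer(replicate))
    yaml::write_yaml(x, path)
    invisible(path)
}

#' Read a truth manifest written by [writeTruthManifest()]
#'
#' @param path manifest file.
#' @return A \linkS4class{TruthManifest}.
#' @export
readTruthManifest <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    x <- yaml::read_yaml(path)
    units <- lapply(x$effect_structure, function(u)
        list(ids = unlist(u$ids), enriched = u$enriched))
    tr <- TruthManifest(units, x$model_name)
    if (!setequal(tr@causalIds, unlist(x$causal_ids)))
        stopf("manifest %s: causal_ids disagree with effect_structure", path)
    tr
}

#' Write a ranking as a three-column TSV (feature_id, score, rank)
#'
#' Scores are printed with 17 significant digits so that a read back
#' reproduces them bit-for-bit.
#'
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeRanking <- function(ranking, path) {
    ord <- rankedFeatures(ranking)
    df <- data.frame(feature_id = ord,
                     score = sprintf("%.17g", featureScores(ranking)[ord]),
                     rank = seq_along(ord))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    attr(path, "method") <- selectorMethod(ranking)
    invisible(path)
}

#' Read a ranking written by [writeRanking()]
#'
#' The file's rank column must be 1..n in row order and consistent with a
#' descending sort of the scores; the row order defines the tie-break.
#'
#' @param path ranking TSV.
#' @param method selector name to attach (the file does not store it).
#' @return A \linkS4class{FeatureRanking}.
#' @export
readRanking <- function(path, method = "unknown") {
    if (!file.exists(path)) stopf("file not found: %s", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("feature_id", "score", "rank")
    if (!all(need %in% colnames(df)))
        stopf("ranking file %s must have columns %s", path,
              paste(need, collapse = ", "))
    if (!identical(as.integer(df$rank), seq_len(nrow(df))))
        stopf("ranking file %s: rank column must be 1..n in row order", path)
    if (is.unsorted(rev(df$score)))
        stopf("ranking file %s: rank order inconsistent with scores", path)
    scores <- stats::setNames(as.numeric(df$score), df$feature_id)
    new("FeatureRanking", method = method, scores = scores,
        order = df$feature_id)
}
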