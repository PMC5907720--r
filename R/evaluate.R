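## Truth-based scoring of selections, replicate aggregation, Venn-region
## overlap counts, and the end-to-end benchmark runner.

#' Sensitivity of a selection against a truth manifest
#'
#' Sensitivity is the proportion of the causal (true-positive) features
#' present in the selected set; 1 means every true positive was selected.
#'
#' @param selected character vector of selected feature IDs.
#' @param truth a \linkS4class{TruthManifest} with at least one causal ID.
#' @return List with \code{sensitivity} in [0, 1], \code{tp} and \code{fp}
#'   counts (tp + fp = number selected).
#' @examples
#' tr <- TruthManifest(list(list(ids = c("G1", "G2"), enriched = "case")),
#'                     "pair")
#' selectionSensitivity(c("G1", "G2", "G50"), tr)
#' @export
selectionSensitivity <- function(selected, truth) {
    ids <- causalIds(truth)
    if (!length(ids)) stopf("sensitivity is undefined for an empty truth")
    selected <- unique(selected)
    tp <- sum(selected %in% ids)
    list(sensitivity = tp / length(ids), tp = as.integer(tp),
         fp = as.integer(length(selected) - tp))
}

#' Average evaluation rows across replicates
#'
#' Arithmetic mean of sensitivity, tp and fp within every
#' (model, method, percentage) group; the replicate field of the output is
#' \code{"mean"} and \code{n} records the number of replicates averaged.
#'
#' @param rows data.frame with columns \code{model}, \code{method},
#'   \code{percentage}, \code{replicate}, \code{sensitivity}, \code{tp},
#'   \code{fp} (the \code{results} table of [runBenchmark()]).
#' @return Aggregated data.frame, one row per group.
#' @export
aggregateReplicates <- function(rows) {
    key <- interaction(rows$model, rows$method, rows$percentage,
                       drop = TRUE)
    out <- do.call(rbind, lapply(split(rows, key), function(g) {
        data.frame(model = g$model[1], method = g$method[1],
                   percentage = g$percentage[1], replicate = "mean",
                   sensitivity = mean(g$sensitivity), tp = mean(g$tp),
                   fp = mean(g$fp), n = nrow(g),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Venn-region counts of per-method selections
#'
#' Counts the features falling in every region of the Venn partition of
#' 2 to 4 selection sets (2^m - 1 regions); the counts sum to the size of
#' the union.
#'
#' @param perMethod named list (2-4 entries) of character vectors, e.g.
#'   \code{perMethodSets(x)} of a \linkS4class{SelectionResult}.
#' @return Named integer vector; region names join the member methods
#'   with \code{"&"}.
#' @examples
#' overlapCounts(list(a = c("x", "y"), b = c("y", "z")))
#' @export
overlapCounts <- function(perMethod) {
    m <- length(perMethod)
    if (m < 2 || m > 4)
        stopf(paste0("overlapCounts supports 2-4 methods (got %d); ",
                     "tabulate the per-method sets directly instead"), m)
    nm <- names(perMethod)
    if (is.null(nm)) nm <- paste0("M", seq_len(m))
    u <- Reduce(union, perMethod, character())
    membership <- vapply(perMethod, function(s) u %in% s,
                         logical(length(u)))
    if (length(u) == 1L) membership <- matrix(membership, nrow = 1)
    out <- integer()
    for (size in seq_len(m))
        for (sub in utils::combn(m, size, simplify = FALSE)) {
            inAll <- rowSums(membership[, sub, drop = FALSE]) == size &
                     rowSums(membership[, -sub, drop = FALSE]) == 0
            if (size == m)
                inAll <- rowSums(membership) == m
            out[paste(nm[sub], collapse = "&")] <- sum(inAll)
        }
    out
}

# selector config for one dataset, merging benchmark-level overrides
.cellSelectorConfig <- function(config, nFeatures, seed) {
    ov <- config$selector
    do.call(selectorConfig, c(
        list(preset = ov$preset %||% "interaction",
             nFeatures = nFeatures, seed = seed),
        ov[setdiff(names(ov), "preset")]))
}

.scoreDataset <- function(ds, methods, percentages, cfg, dropFraction,
                          modelName, rep) {
    rankings <- stats::setNames(
        lapply(methods, function(m)
            rankFeatures(ds, m, cfg, dropFraction = dropFraction)),
        methods)
    truth <- truthManifest(ds)
    rows <- list()
    sels <- list()
    for (p in percentages) {
        sel <- collectiveUnion(rankings, p)
        sets <- c(perMethodSets(sel), list(union = unionSet(sel)))
        for (m in names(sets)) {
            s <- selectionSensitivity(sets[[m]], truth)
            rows[[length(rows) + 1L]] <- data.frame(
                model = modelName, method = m, percentage = p,
                replicate = rep, sensitivity = s$sensitivity,
                tp = s$tp, fp = s$fp, n_selected = length(sets[[m]]),
                stringsAsFactors = FALSE)
        }
        sels[[as.character(p)]] <- sel
    }
    list(rows = rows, selections = sels, causal = causalIds(truth))
}

#' Run a full simulation benchmark
#'
#' Simulates every grid cell, runs each selector, forms per-method and
#' collective (union) selections at each percentage, scores them against
#' the truth manifests, and aggregates. Per-cell seeds are derived from
#' the master seed, so results do not depend on execution order, and any
#' per-cell failure is recorded while the benchmark continues.
#'
#' @param config a list describing the run:
#'   \describe{
#'   \item{experiment}{\code{"freq"} or \code{"gametes"}.}
#'   \item{methods}{character vector of [rankFeatures()] method names.}
#'   \item{percentages}{top percentages (default \code{c(3, 5, 10)}).}
#'   \item{replicates}{replicates per grid cell (study scale: 10 for freq,
#'     50 for gametes).}
#'   \item{seed}{master seed.}
#'   \item{selector}{optional list of [selectorConfig()] overrides, e.g.
#'     \code{list(preset = "interaction", rfTrees = 1000)}.}
#'   \item{dropFraction}{TuRF elimination fraction (default 0.1).}
#'   \item{freq grid}{\code{models} (model names), \code{signals}
#'     (default \code{c(0.1, 0.5, 0.9)}), \code{nSnps} (100),
#'     \code{nCases}/\code{nControls} (2000).}
#'   \item{gametes grid}{\code{h2} (default \code{c(0.1, 0.2, 0.4)},
#'     the component models' heritability), \code{architectures}
#'     (\code{c("easy", "hard")}), \code{maf} (0.2), \code{prevalence}
#'     (default: h2-adaptive, see [randomPureEpistasisModel()]),
#'     \code{mainShare} (main-effect mixing weight, 1/3),
#'     \code{candidates} (10000 models scanned for the ease-of-detection
#'     extremes), \code{nSnps} (100), \code{nCases}/\code{nControls}
#'     (1000).}
#'   }
#' @return List with \code{results} (long-format data.frame: one row per
#'   model x method-or-union x percentage x replicate), \code{means}
#'   (replicate aggregate), \code{selections} (per dataset), and for the
#'   gametes experiment \code{pooledTruePositives} (architecture x
#'   percentage matrix of distinct true positives recovered by the union,
#'   pooled over heritabilities as in the merged-architecture analysis)
#'   and \code{overlap} (per architecture and percentage, Venn-region
#'   counts of the pooled per-method selections when 2-4 methods are run).
#'   Failed cells are listed in \code{errors}.
#' @export
runBenchmark <- function(config) {
    experiment <- match.arg(config$experiment, c("freq", "gametes"))
    methods <- config$methods %||% c("mdr", "rf", "gbm", "turf")
    percentages <- config$percentages %||% c(3, 5, 10)
    # study-scale replicate defaults: 10 per cell (freq), 50 (gametes)
    replicates <- config$replicates %||%
        if (identical(config$experiment, "freq")) 10L else 50L
    seed <- config$seed %||% 1L
    dropFraction <- config$dropFraction %||% 0.1
    if (experiment == "freq")
        .runFreqBenchmark(config, methods, percentages, replicates, seed,
                          dropFraction)
    else
        .runGametesBenchmark(config, methods, percentages, replicates,
                             seed, dropFraction)
}

.runFreqBenchmark <- function(config, methods, percentages, replicates,
                              seed, dropFraction) {
    models <- config$models %||% c("1SNP", "2SNP", "3SNP", "4SNP",
        "case1_control0", "case1_control1", "case2_control0",
        "case2_control2")
    signals <- config$signals %||% c(0.1, 0.5, 0.9)
    nSnps <- config$nSnps %||% 100
    nCases <- config$nCases %||% 2000
    nControls <- config$nControls %||% 2000
    grid <- expand.grid(model = models, signal = signals,
                        stringsAsFactors = FALSE)
    rows <- list(); sels <- list(); errs <- list()
    for (ci in seq_len(nrow(grid))) {
        spec <- freqEffectSpec(grid$model[ci], grid$signal[ci],
                               maf = config$maf %||% 0.4)
        nameCi <- sprintf("%s_s%g", grid$model[ci], grid$signal[ci])
        for (rep in seq_len(replicates)) {
            res <- tryCatch({
                sd <- deriveSeed(seed, ci, rep)
                ds <- simulateFreqData(spec, nSnps, nCases, nControls,
                                       seed = sd, replicate = rep)
                cfg <- .cellSelectorConfig(config, nSnps, sd)
                .scoreDataset(ds, methods, percentages, cfg,
                              dropFraction, nameCi, rep)
            }, error = function(e) e)
            if (inherits(res, "error")) {
                errs[[sprintf("%s_r%d", nameCi, rep)]] <-
                    conditionMessage(res)
                next
            }
            rows <- c(rows, res$rows)
            sels[[sprintf("%s_r%d", nameCi, rep)]] <-
                list(selections = res$selections, causal = res$causal)
        }
    }
    results <- do.call(rbind, rows)
    list(results = results, means = aggregateReplicates(results),
         selections = sels, errors = errs)
}

.runGametesBenchmark <- function(config, methods, percentages, replicates,
                                 seed, dropFraction) {
    h2grid <- config$h2 %||% c(0.1, 0.2, 0.4)
    archs <- config$architectures %||% c("easy", "hard")
    maf <- config$maf %||% 0.2
    K <- config$prevalence          # NULL: adaptive default per h2
    mainShare <- config$mainShare %||% (1 / 3)
    candidates <- config$candidates %||% 10000
    nSnps <- config$nSnps %||% 100
    nCases <- config$nCases %||% 1000
    nControls <- config$nControls %||% 1000
    ## per h2: scan one candidate pair population for the detection
    ## extremes, then mix in the additive main effect
    modelsByH2 <- lapply(seq_along(h2grid), function(hi) {
        h2 <- h2grid[hi]
        pop <- samplePurePairModels(candidates, maf, h2 = h2,
                                    prevalence = K,
                                    seed = deriveSeed(seed, 9000 + hi, 0))
        ex <- selectEdmExtremes(pop)
        main <- mainEffectPenetrance(maf, h2)
        list(easy = combineWithMainEffect(ex$easy, main, mainShare),
             hard = combineWithMainEffect(ex$hard, main, mainShare))
    })
    rows <- list(); sels <- list(); errs <- list()
    ci <- 0L
    for (ai in seq_along(archs))
        for (hi in seq_along(h2grid)) {
            ci <- ci + 1L
            arch <- archs[ai]
            nameCi <- sprintf("gametes_%s_h%g", arch, h2grid[hi])
            model <- modelsByH2[[hi]][[arch]]
            for (rep in seq_len(replicates)) {
                res <- tryCatch({
                    sd <- deriveSeed(seed, ci, rep)
                    ds <- simulateGametesData(model, nSnps, nCases,
                        nControls, seed = sd, modelName = nameCi,
                        replicate = rep)
                    cfg <- .cellSelectorConfig(config, nSnps, sd)
                    .scoreDataset(ds, methods, percentages, cfg,
                                  dropFraction, nameCi, rep)
                }, error = function(e) e)
                if (inherits(res, "error")) {
                    errs[[sprintf("%s_r%d", nameCi, rep)]] <-
                        conditionMessage(res)
                    next
                }
                rows <- c(rows, res$rows)
                sels[[sprintf("%s_r%d", nameCi, rep)]] <-
                    list(selections = res$selections, causal = res$causal)
            }
        }
    results <- do.call(rbind, rows)
    out <- list(results = results, means = aggregateReplicates(results),
                selections = sels, errors = errs)
    ## pooled distinct true positives recovered by the union, merging the
    ## heritability levels within one architecture (each level contributes
    ## its own 3 causal loci)
    pooled <- matrix(0L, length(archs), length(percentages),
                     dimnames = list(archs, as.character(percentages)))
    overlap <- list()
    for (arch in archs) {
        for (p in as.character(percentages)) {
            tot <- 0L
            poolSets <- stats::setNames(
                vector("list", length(methods)), methods)
            for (h2 in h2grid) {
                nameCi <- sprintf("gametes_%s_h%g", arch, h2)
                reps <- sels[grep(paste0("^", nameCi, "_r"), names(sels))]
                if (!length(reps)) next
                got <- character()
                for (r in reps) {
                    sel <- r$selections[[p]]
                    got <- union(got, intersect(unionSet(sel), r$causal))
                    for (m in methods)
                        poolSets[[m]] <- union(poolSets[[m]],
                            paste0(h2, ":", perMethodSets(sel)[[m]]))
                }
                tot <- tot + length(got)
            }
            pooled[arch, p] <- tot
            if (length(methods) >= 2 && length(methods) <= 4)
                overlap[[arch]][[p]] <- overlapCounts(poolSets)
        }
    }
    out$pooledTruePositives <- pooled
    out$overlap <- overlap
    out
}
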