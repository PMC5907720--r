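# Independent brute-force oracles and small dataset builders used across
# the suite. The oracles are literal, loop-based transcriptions of the
# algorithm definitions, kept free of the vectorised implementation code.

# random SnpDataset with HWE-ish genotypes and a random balanced-ish label
randomDataset <- function(n, p, seed, maf = 0.3) {
    withr::with_seed(seed, {
        probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
        g <- matrix(sample(0:2, n * p, TRUE, prob = probs), n, p)
        y <- c(0L, 1L, sample(0:1, n - 2, TRUE))  # both classes present
        SnpDataset(g, status = y)
    })
}

# literal MDR: enumerate cells of a 1- or 2-locus model by string keys,
# label high iff cases/controls ratio strictly exceeds the overall ratio
# (empty or tied cells low), score by balanced accuracy
mdrOracleBA <- function(X, y, loci) {
    key <- apply(X[, loci, drop = FALSE], 1, paste, collapse = ":")
    nCase <- sum(y == 1)
    nCtrl <- sum(y == 0)
    tp <- 0
    tn <- 0
    for (cell in unique(key)) {
        inCell <- key == cell
        ca <- sum(y == 1 & inCell)
        co <- sum(y == 0 & inCell)
        high <- (ca / nCase) > (co / nCtrl)
        if (high) tp <- tp + ca else tn <- tn + co
    }
    # cells absent from the data are empty -> low-risk, contribute no
    # controls, so the enumeration over observed cells is complete
    0.5 * (tp / nCase + tn / nCtrl)
}

mdrOracleScores <- function(X, y) {
    p <- ncol(X)
    best <- vapply(seq_len(p), function(j) mdrOracleBA(X, y, j),
                   numeric(1))
    if (p >= 2)
        for (j in seq_len(p - 1))
            for (k in (j + 1):p) {
                ba <- mdrOracleBA(X, y, c(j, k))
                best[j] <- max(best[j], ba)
                best[k] <- max(best[k], ba)
            }
    best
}

# literal pairwise MultiSURF*: per-target mean/sd distance thresholds with
# a dead band of half a standard deviation, near pairs scored
# conventionally and far pairs inverted, everything in explicit loops
multisurfOracle <- function(X, y) {
    n <- nrow(X)
    p <- ncol(X)
    D <- matrix(0, n, n)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (i != j)
                D[i, j] <- mean(abs(X[i, ] - X[j, ]) / 2)
    s <- numeric(p)
    for (i in seq_len(n)) {
        d <- D[i, -i]
        Tm <- mean(d)
        band <- stats::sd(d) / 2
        for (j in seq_len(n)) {
            if (j == i) next
            near <- D[i, j] < Tm - band
            far <- D[i, j] > Tm + band
            if (!near && !far) next
            hit <- y[i] == y[j]
            sgn <- if (near) (if (hit) -1 else +1) else
                             (if (hit) +1 else -1)
            for (a in seq_len(p))
                s[a] <- s[a] + sgn * abs(X[i, a] - X[j, a]) / 2
        }
    }
    s / n
}
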