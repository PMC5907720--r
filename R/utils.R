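# Internal helpers shared across modules.

#' Evaluate an expression with a locally-set RNG seed
#'
#' Saves and restores the caller's RNG state so seeded operations do not
#' perturb the global stream.
#' @noRd
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

#' Derive a per-cell, per-replicate seed from a master seed
#'
#' Deterministic mixing that keeps the result a valid 32-bit integer, so one
#' master seed reproduces every replicate independently of execution order.
#' @noRd
deriveSeed <- function(master, cell = 0L, replicate = 0L) {
    m <- 2147483629
    s <- (as.numeric(master) %% m)
    s <- (s * 48271 + as.numeric(cell) * 1000003 +
          as.numeric(replicate) * 7919 + 12345) %% m
    as.integer(s + 1)
}

# round-half-up (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

# Hardy-Weinberg genotype probabilities for codes (0, 1, 2) at MAF q
hweProbs <- function(q) {
    stopifnot(q > 0, q <= 0.5)
    c((1 - q)^2, 2 * q * (1 - q), q^2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
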