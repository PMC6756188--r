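#' Derive a child seed from a master seed
#'
#' All randomness in the package flows root -> stage -> autosome -> iteration
#' through this fixed mixing function, so that a single master seed makes
#' every downstream draw reproducible without shared global RNG state.  The
#' mix is a multiplicative-congruential scramble of the seed with each key in
#' turn, reduced modulo 2^31 - 1; all intermediate products stay below 2^53
#' and are exact in double arithmetic.
#'
#' @param seed integer master seed (0 <= seed < 2^31).
#' @param ... integer keys identifying the consumer (stage index, autosome
#'   index, iteration index, ...).
#' @return an integer seed in [1, 2^31 - 2], usable with [set.seed()].
#' @export
#' @examples
#' mixSeed(1, 3, 7)
mixSeed <- function(seed, ...) {
    m <- 2147483647
    s <- as.numeric(seed) %% m
    for (k in c(...)) {
        s <- (s * 69069 + (as.numeric(k) %% m) * 40014 + 12345) %% m
    }
    as.integer(s %% (m - 2) + 1)
}

## run expr under a local RNG seeded with `seed`, restoring caller RNG state
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## required-columns check for the package's TSV dialects
checkColumns <- function(df, cols, what) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stopf("%s: missing column(s) %s", what, paste(miss, collapse = ", "))
    invisible(df)
}
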