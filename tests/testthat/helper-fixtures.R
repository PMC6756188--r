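## Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## fragments GRanges from parallel vectors
fragGR <- function(starts, ends, ids = NULL, src = NULL, side = 0L,
                   chrom = "1") {
    n <- length(starts)
    if (is.null(ids)) ids <- sprintf("f%03d", seq_len(n))
    if (is.null(src)) ids -> src
    GRanges(rep_len(chrom, n), IRanges(starts, ends),
            fragment_id = ids,
            source_sample = rep_len(src, n),
            source_side = rep_len(as.integer(side), n),
            ancestry = rep("NAT", n),
            n_windows = rep(1L, n))
}

## random fragment pool on a small span
randomPool <- function(n, seed, spanMax = 1000L) {
    set.seed(seed)
    s <- sample.int(spanMax - 1L, n, replace = TRUE)
    len <- pmin(spanMax - s, 1L + stats::rgeom(n, 1 / 80))
    fragGR(s, s + len, src = sprintf("ind%02d", sample.int(8, n, TRUE)))
}

## literal re-trace of the published rearrangement procedure: linear scans
## over an explicit list, per-bp boolean coverage. Independent of the
## package's binary-search/tiling implementation.
oracleRearrange <- function(sortedPool, span) {
    pool <- data.frame(id = sortedPool$fragment_id,
                       s = start(sortedPool), e = end(sortedPool),
                       stringsAsFactors = FALSE)
    out <- list()
    while (nrow(pool) > 0) {
        placed <- character()
        lastEnd <- -Inf
        drop <- integer()
        for (i in seq_len(nrow(pool))) {
            if (pool$s[i] > lastEnd) {
                placed <- c(placed, pool$id[i])
                lastEnd <- pool$e[i]
                drop <- c(drop, i)
            }
        }
        covered <- rep(FALSE, span[2] - span[1] + 1)
        for (i in drop) {
            lo <- max(pool$s[i], span[1]); hi <- min(pool$e[i], span[2])
            if (hi >= lo)
                covered[(lo:hi) - span[1] + 1] <- TRUE
        }
        out[[length(out) + 1L]] <- list(ids = placed,
                                        coverage = mean(covered))
        pool <- pool[-drop, , drop = FALSE]
    }
    out
}

## small deterministic phased panel
toyPanel <- function(alleles, chrom = "1", pos = NULL, cm = NULL,
                     samples = NULL, pop = NULL) {
    alleles <- as.matrix(alleles)
    n <- nrow(alleles)
    if (is.null(pos)) pos <- seq_len(n) * 10L
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(alleles) / 2))
    sites <- data.frame(chrom = rep_len(chrom, n), pos_bp = pos,
                        ref = rep_len("A", n), alt = rep_len("G", n))
    if (!is.null(cm)) sites$cm <- cm
    HaplotypePanel(alleles, sites, rep(samples, each = 2),
                   rep(0:1, length(samples)), population = pop)
}

## panel of nHap haplotypes drawn from given per-site frequencies
freqPanel <- function(freq, nHap, seed, prefix = "p", cm = NULL,
                      pop = NULL) {
    set.seed(seed)
    al <- matrix(rbinom(length(freq) * nHap, 1L, rep(freq, nHap)),
                 nrow = length(freq))
    toyPanel(al, cm = if (is.null(cm))
                 seq(0, 100, length.out = length(freq)) else cm,
             samples = sprintf("%s%03d", prefix, seq_len(nHap / 2)),
             pop = if (is.null(pop)) NULL else rep(pop, nHap))
}

## Hudson FST estimator (oracle for the Balding-Nichols simulator)
hudsonFst <- function(p1, p2, n1, n2) {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    mean(num) / mean(den)
}

## window-calls data.frame builder
callRows <- function(starts, ends, post, sample = "s1", side = 0L,
                     chrom = "1", labels = c("NAT", "EUR", "AFR")) {
    df <- data.frame(chrom = chrom, start_bp = starts, end_bp = ends,
                     sample_id = sample, side = side)
    for (j in seq_along(labels)) df[[labels[j]]] <- post[, j]
    df
}

## posterior matrix with mass p on NAT, rest split evenly
natPost <- function(p) cbind(p, (1 - p) / 2, (1 - p) / 2)
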