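#' Sort a fragment pool by start position with random tie order
#'
#' Fragments are ordered by ascending start base pair; fragments sharing a
#' start position are permuted uniformly at random.  This seeded tie order
#' is the only source of randomness in a rearrangement iteration: pools with
#' no shared start positions sort identically under every seed.
#'
#' @param fragments fragments \code{GRanges} (one chromosome).
#' @param seed integer seed for the tie permutation.
#' @return the same \code{GRanges}, reordered.
#' @export
sortPool <- function(fragments, seed) {
    if (length(unique(as.character(seqnames(fragments)))) > 1)
        stopf("sortPool: fragments span more than one chromosome")
    if (length(fragments) == 0) return(fragments)
    tie <- withSeed(seed, sample.int(length(fragments)))
    fragments[order(start(fragments), tie)]
}

## clip sorted non-overlapping placements to a span; derive gaps + coverage
makeRearranged <- function(placements, chrom, span, threshold) {
    spanLen <- span[2] - span[1] + 1L
    if (length(placements)) {
        cs <- pmax(start(placements), span[1])
        ce <- pmin(end(placements), span[2])
        keep <- ce >= cs
        cs <- cs[keep]; ce <- ce[keep]
    } else cs <- ce <- integer()
    covered <- sum(as.numeric(ce - cs + 1L))
    bounds <- c(span[1], if (length(cs)) as.vector(rbind(cs, ce + 1L)),
                span[2] + 1L)
    gs <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)] - 1L
    ok <- ge >= gs
    gaps <- GRanges(rep(chrom, sum(ok)), IRanges(gs[ok], ge[ok]))
    cov <- covered / spanLen
    new("RearrangedChromosome", chrom = chrom, placements = placements,
        gaps = gaps, span = as.integer(span), coverage = cov,
        retained = cov >= threshold)
}

#' One greedy tiling pass over an ordered pool
#'
#' Scans the pool left to right and places a fragment whenever its start
#' base pair is strictly greater than the end of the last placed fragment
#' (the first fragment is always placed).  Where the next placement does not
#' start at the immediately following base pair, the skipped interval is
#' recorded as a gap (missing sequence).  Placed fragments are consumed; all
#' others remain available for subsequent passes.
#'
#' @param pool fragments \code{GRanges} already ordered by [sortPool()].
#' @param span integer (first_bp, last_bp): chromosome span used as coverage
#'   denominator.
#' @param threshold retention coverage threshold (default 0.95).
#' @return list with elements \code{chromosome}
#'   (\linkS4class{RearrangedChromosome}) and \code{placedIdx} (indices into
#'   \code{pool} of the consumed fragments).
#' @export
tileOnce <- function(pool, span, threshold = 0.95) {
    if (length(pool) == 0) stopf("tileOnce: empty pool")
    starts <- start(pool); ends <- end(pool)
    ## pool is sorted by start: the next placeable fragment is the first one
    ## with start > lastEnd, found by binary search; identical to a literal
    ## left-to-right scan that skips overlapping fragments
    placed <- integer(length(pool)); np <- 0L; idx <- 1L
    n <- length(pool)
    while (idx <= n) {
        np <- np + 1L
        placed[np] <- idx
        idx <- findInterval(ends[idx], starts) + 1L
    }
    placed <- placed[seq_len(np)]
    chrom <- as.character(seqnames(pool))[1]
    list(chromosome = makeRearranged(pool[placed], chrom, span, threshold),
         placedIdx = placed)
}

## integer-vector core of one iteration: repeated greedy passes over a pool
## already sorted by (start, tie).  Returns the per-pass placed indices and
## coverages without constructing any S4 objects, so iteration search stays
## cheap; the winning iteration is rebuilt as S4 afterwards.
jigsawPasses <- function(starts, ends, span) {
    spanLen <- span[2] - span[1] + 1
    remaining <- seq_along(starts)
    passes <- list(); coverages <- numeric()
    while (length(remaining)) {
        s <- starts[remaining]; e <- ends[remaining]
        m <- length(remaining)
        placed <- integer(m); np <- 0L; idx <- 1L
        while (idx <= m) {
            np <- np + 1L
            placed[np] <- idx
            idx <- findInterval(e[idx], s) + 1L
        }
        placed <- placed[seq_len(np)]
        cs <- pmax(s[placed], span[1]); ce <- pmin(e[placed], span[2])
        coverages <- c(coverages,
                       sum(as.numeric(pmax(0, ce - cs + 1))) / spanLen)
        passes[[length(passes) + 1L]] <- remaining[placed]
        remaining <- remaining[-placed]
    }
    list(passes = passes, coverages = coverages)
}

#' One full rearrangement iteration
#'
#' Sorts the fragment pool once (seeded tie order), then repeats greedy
#' tiling passes ([tileOnce()]) on the remaining pool until it is empty, so
#' that no fragment is used twice.  Chromosomes with coverage at or above
#' \code{threshold} are flagged retained and counted; below-threshold
#' chromosomes are recorded but unusable (their fragments stay consumed
#' within the iteration).
#'
#' @param fragments fragments \code{GRanges} (one chromosome).
#' @param span integer (first_bp, last_bp).
#' @param threshold retention coverage threshold; default 0.95.
#' @param seed integer seed for the tie order.
#' @param iteration iteration index recorded in the result.
#' @return an \linkS4class{IterationResult}.
#' @export
rearrangeIteration <- function(fragments, span, threshold = 0.95, seed = 1L,
                               iteration = 0L) {
    pool <- sortPool(fragments, seed)
    chrom <- if (length(pool)) as.character(seqnames(pool))[1]
             else NA_character_
    jp <- jigsawPasses(start(pool), end(pool), span)
    chroms <- lapply(jp$passes, function(idx)
        makeRearranged(pool[idx], chrom, span, threshold))
    nAbove <- sum(vapply(chroms, function(ch) ch@retained, logical(1)))
    new("IterationResult", iteration = as.integer(iteration),
        seed = as.numeric(seed), chrom = chrom, chromosomes = chroms,
        threshold = threshold, nAboveThreshold = as.integer(nAbove))
}

#' Select the best of n seeded rearrangement iterations
#'
#' Runs \code{nIter} independent iterations whose tie-order seeds are
#' derived deterministically from \code{masterSeed} (via [mixSeed()]) and
#' returns the iteration with the most chromosomes above the coverage
#' threshold; ties break to the lowest iteration index, making the result
#' bit-reproducible for a given master seed.
#'
#' @param fragments fragments \code{GRanges} (one chromosome).
#' @param span integer (first_bp, last_bp).
#' @param threshold retention coverage threshold; default 0.95.
#' @param nIter number of iterations; default 100.
#' @param masterSeed master seed.
#' @return the winning \linkS4class{IterationResult}; the per-iteration
#'   retained counts are attached as \code{attr(x, "iterationCounts")}.
#' @export
bestIteration <- function(fragments, span, threshold = 0.95, nIter = 100L,
                          masterSeed = 1L) {
    if (nIter < 1) stopf("nIter must be >= 1")
    s0 <- start(fragments); e0 <- end(fragments)
    counts <- integer(nIter)
    for (it in seq_len(nIter)) {
        seed <- mixSeed(masterSeed, 101L, it)
        tie <- withSeed(seed, sample.int(length(s0)))
        ord <- order(s0, tie)
        jp <- jigsawPasses(s0[ord], e0[ord], span)
        counts[it] <- sum(jp$coverages >= threshold)
    }
    bestIt <- which.max(counts)   # ties break to the lowest index
    best <- rearrangeIteration(fragments, span, threshold,
                               seed = mixSeed(masterSeed, 101L, bestIt),
                               iteration = bestIt - 1L)
    attr(best, "iterationCounts") <- counts
    best
}

#' @rdname jigsaw-accessors
#' @export
setMethod("nAboveThreshold", "IterationResult", function(x) x@nAboveThreshold)

#' @rdname RearrangedChromosome-accessors
#' @export
setMethod("placements", "RearrangedChromosome", function(x) x@placements)

#' @rdname RearrangedChromosome-accessors
#' @export
setMethod("fragmentGaps", "RearrangedChromosome", function(x) x@gaps)

#' @rdname RearrangedChromosome-accessors
#' @export
setMethod("spanCoverage", "RearrangedChromosome", function(x) x@coverage)

setMethod("show", "RearrangedChromosome", function(object) {
    cat(sprintf(
        "RearrangedChromosome %s: %d placements, %d gaps, coverage %.4f%s\n",
        object@chrom, length(object@placements), length(object@gaps),
        object@coverage, if (object@retained) " (retained)" else ""))
})

setMethod("show", "IterationResult", function(object) {
    cat(sprintf(
        "IterationResult %d (chrom %s): %d chromosomes, %d above threshold %.2f\n",
        object@iteration, object@chrom, length(object@chromosomes),
        object@nAboveThreshold, object@threshold))
})

#' Pair retained chromosomes into reconstructed diploid individuals
#'
#' The autosome with the fewest retained rearranged chromosomes sets the
#' number of reconstructed chromosomes; the number of individuals is half
#' that count (rounded down).  Per autosome, retained chromosomes are
#' shuffled with a seed derived from \code{seed} and consecutive pairs
#' become one individual's chromosome pair; excess chromosomes are
#' discarded.  If any autosome retains no chromosome (or the minimum allows
#' no pair) the cohort reports \code{"no reconstruction possible"}.
#'
#' @param perAutosome named list of \linkS4class{IterationResult}, one per
#'   autosome.
#' @param seed integer seed for the pairing shuffle.
#' @param prefix identifier prefix for reconstructed individuals.
#' @return a \linkS4class{ReconstructedCohort}.
#' @export
assemblePopulation <- function(perAutosome, seed = 1L, prefix = "RI") {
    if (!length(perAutosome)) stopf("no autosomes supplied")
    if (is.null(names(perAutosome)))
        names(perAutosome) <- vapply(perAutosome, function(x) x@chrom,
                                     character(1))
    counts <- vapply(perAutosome, nAboveThreshold, integer(1))
    nInd <- min(counts) %/% 2L
    if (nInd == 0L)
        return(new("ReconstructedCohort", individuals = list(),
                   status = "no reconstruction possible",
                   nRetained = counts))
    perAutoPairs <- lapply(seq_along(perAutosome), function(ai) {
        res <- perAutosome[[ai]]
        ret <- Filter(function(ch) ch@retained, res@chromosomes)
        ord <- withSeed(mixSeed(seed, 9901L, ai), sample.int(length(ret)))
        ret[ord][seq_len(2L * nInd)]
    })
    inds <- lapply(seq_len(nInd), function(i) {
        chrs <- lapply(perAutoPairs, function(p) p[c(2L * i - 1L, 2L * i)])
        names(chrs) <- names(perAutosome)
        new("ReconstructedIndividual",
            id = sprintf("%s%03d", prefix, i), chromosomes = chrs)
    })
    new("ReconstructedCohort", individuals = inds, status = "ok",
        nRetained = counts)
}

#' @rdname jigsaw-accessors
#' @export
setMethod("individuals", "ReconstructedCohort", function(x) x@individuals)

#' @rdname jigsaw-accessors
#' @export
setMethod("reconstructionStatus", "ReconstructedCohort",
          function(x) x@status)

setMethod("show", "ReconstructedCohort", function(object) {
    cat(sprintf("ReconstructedCohort: %d individuals (status: %s)\n",
                length(object@individuals), object@status))
    if (length(object@nRetained))
        cat("  retained chromosomes:",
            paste(sprintf("%s=%d", names(object@nRetained),
                          object@nRetained), collapse = ", "), "\n")
})

setMethod("show", "ReconstructedIndividual", function(object) {
    cat(sprintf("ReconstructedIndividual %s: %d autosome pair(s)\n",
                object@id, length(object@chromosomes)))
})

## copy one rearranged chromosome's alleles out of the source panel;
## returns the haplotype plus a count of placements containing no sites
materializeHaplotype <- function(rc, panel, pos, colKey) {
    hap <- rep(NA_integer_, length(pos))
    p <- rc@placements
    if (length(p) == 0) return(list(hap = hap, nEmpty = 0L))
    s <- start(p); e <- end(p)
    src <- match(paste(p$source_sample, p$source_side), colKey)
    if (anyNA(src)) stopf("fragment source haplotype absent from panel")
    a <- assay(panel, "alleles")
    nEmpty <- 0L
    for (k in seq_along(p)) {
        i1 <- findInterval(s[k] - 1L, pos) + 1L
        i2 <- findInterval(e[k], pos)
        if (i2 < i1) {
            nEmpty <- nEmpty + 1L
            next
        }
        hap[i1:i2] <- a[i1:i2, src[k]]
    }
    list(hap = hap, nEmpty = nEmpty)
}

#' Materialize reconstructed genotypes from the source panel
#'
#' For every site inside a placed fragment, the reconstructed haplotype
#' carries the source haplotype's allele at that site (fragment-internal
#' phase is preserved exactly); sites inside gaps are missing.
#'
#' @param individual a \linkS4class{ReconstructedIndividual}.
#' @param panel the source (admixed) \linkS4class{HaplotypePanel}.
#' @return integer matrix, sites x 2 haplotypes, with \code{NA} in gaps.
#' @seealso [materializeCohort()] for whole-cohort materialization with gap
#'   masks.
#' @export
materializeGenotypes <- function(individual, panel) {
    chroms <- as.character(seqnames(rowRanges(panel)))
    pos <- GenomicRanges::start(rowRanges(panel))
    colKey <- paste(haplotypeSample(panel), haplotypeSide(panel))
    out <- matrix(NA_integer_, nrow(panel), 2L)
    nEmpty <- 0L
    for (auto in names(individual@chromosomes)) {
        i <- which(chroms == auto)
        if (!length(i)) next
        sub <- panel[i, ]
        for (sidek in 1:2) {
            rc <- individual@chromosomes[[auto]][[sidek]]
            mh <- materializeHaplotype(rc, sub, pos[i], colKey)
            out[i, sidek] <- mh$hap
            nEmpty <- nEmpty + mh$nEmpty
        }
    }
    if (nEmpty > 0)
        warning(sprintf("%s: %d placed fragment(s) span no panel sites",
                        individual@id, nEmpty))
    out
}

#' Materialize a whole reconstructed cohort
#'
#' @param cohort a \linkS4class{ReconstructedCohort} with status
#'   \code{"ok"}.
#' @param panel the source (admixed) \linkS4class{HaplotypePanel}.
#' @param population population label assigned to the reconstructed
#'   individuals.
#' @return list with \code{panel} (a \linkS4class{HaplotypePanel} of the
#'   reconstructed individuals; gap sites are missing alleles) and
#'   \code{gaps} (a \code{data.frame} per-haplotype gap mask with columns
#'   \code{chrom}, \code{start_bp}, \code{end_bp}, \code{individual},
#'   \code{side}).
#' @export
materializeCohort <- function(cohort, panel, population = "reconstructed") {
    if (cohort@status != "ok") stopf("cohort status: %s", cohort@status)
    inds <- cohort@individuals
    mats <- lapply(inds, materializeGenotypes, panel = panel)
    al <- do.call(cbind, mats)
    rr <- rowRanges(panel)
    ids <- vapply(inds, function(x) x@id, character(1))
    gapRows <- list()
    for (ind in inds) for (auto in names(ind@chromosomes))
        for (sidek in 1:2) {
            g <- ind@chromosomes[[auto]][[sidek]]@gaps
            if (length(g))
                gapRows[[length(gapRows) + 1L]] <- data.frame(
                    chrom = auto, start_bp = start(g), end_bp = end(g),
                    individual = ind@id, side = sidek - 1L)
        }
    gaps <- if (length(gapRows)) do.call(rbind, gapRows)
            else data.frame(chrom = character(), start_bp = integer(),
                            end_bp = integer(), individual = character(),
                            side = integer())
    rpanel <- HaplotypePanel(
        al,
        data.frame(chrom = as.character(seqnames(rr)),
                   pos_bp = GenomicRanges::start(rr),
                   ref = rr$ref, alt = rr$alt, cm = rr$cm),
        rep(ids, each = 2), rep(0:1, length(ids)),
        population = rep(population, 2L * length(ids)))
    list(panel = rpanel, gaps = gaps)
}

## per-bp source sample of one haplotype at elementary breakpoints
sourceAt <- function(rc, at) {
    p <- rc@placements
    if (length(p) == 0) return(rep(NA_character_, length(at)))
    idx <- findInterval(at, start(p))
    src <- rep(NA_character_, length(at))
    ok <- idx >= 1
    okk <- which(ok)[at[ok] <= end(p)[idx[ok]]]
    src[okk] <- p$source_sample[idx[okk]]
    src
}

#' Pairwise shared-source-sample fraction of reconstructed individuals
#'
#' Because fragments from a single admixed individual can end up in
#' different reconstructed individuals, apparent relatedness among
#' reconstructions is an artifact to monitor.  Entry (i, j) is the fraction
#' of genome base pairs where individuals i and j both carry fragments
#' sourced from the same admixed individual; the diagonal applies the same
#' measure between an individual's two haplotypes.
#'
#' @param individuals list of \linkS4class{ReconstructedIndividual} (all
#'   built over the same autosome spans).
#' @return symmetric numeric matrix with one row per individual.
#' @export
sourceOverlap <- function(individuals) {
    if (length(individuals) < 1) stopf("need at least one individual")
    autos <- names(individuals[[1]]@chromosomes)
    spans <- lapply(autos, function(a)
        individuals[[1]]@chromosomes[[a]][[1]]@span)
    genome <- sum(vapply(spans, function(s) s[2] - s[1] + 1, numeric(1)))
    n <- length(individuals)
    m <- matrix(0, n, n,
                dimnames = rep(list(vapply(individuals, function(x) x@id,
                                           character(1))), 2))
    for (ai in seq_along(autos)) {
        a <- autos[[ai]]; span <- spans[[ai]]
        placed <- lapply(individuals, function(ind)
            lapply(ind@chromosomes[[a]], function(rc) rc))
        for (i in seq_len(n)) for (j in i:n) {
            rcs_i <- placed[[i]]; rcs_j <- placed[[j]]
            bp <- sort(unique(c(span[1], span[2] + 1,
                unlist(lapply(c(rcs_i, rcs_j), function(rc)
                    c(start(rc@placements), end(rc@placements) + 1L))))))
            bp <- bp[bp >= span[1] & bp <= span[2] + 1]
            at <- bp[-length(bp)]
            len <- diff(bp)
            if (i == j) {
                s1 <- sourceAt(rcs_i[[1]], at); s2 <- sourceAt(rcs_i[[2]], at)
                hit <- !is.na(s1) & !is.na(s2) & s1 == s2
            } else {
                si <- cbind(sourceAt(rcs_i[[1]], at), sourceAt(rcs_i[[2]], at))
                sj <- cbind(sourceAt(rcs_j[[1]], at), sourceAt(rcs_j[[2]], at))
                hit <- (!is.na(si[, 1]) & (
                            (!is.na(sj[, 1]) & si[, 1] == sj[, 1]) |
                            (!is.na(sj[, 2]) & si[, 1] == sj[, 2]))) |
                       (!is.na(si[, 2]) & (
                            (!is.na(sj[, 1]) & si[, 2] == sj[, 1]) |
                            (!is.na(sj[, 2]) & si[, 2] == sj[, 2])))
            }
            m[i, j] <- m[i, j] + sum(len[hit])
            m[j, i] <- m[i, j]
        }
    }
    m / genome
}

#' Reconstruct one population from its fragment pool
#'
#' Convenience wrapper chaining [bestIteration()] (per autosome),
#' [assemblePopulation()] and [materializeCohort()] for a single fragment
#' pool, e.g. one deme's target-ancestry fragments.
#'
#' @param fragments fragments \code{GRanges}.
#' @param panel the source (admixed) \linkS4class{HaplotypePanel}.
#' @param spans named list chrom -> integer (first_bp, last_bp); default
#'   from [panelSpans()].
#' @param threshold retention coverage threshold; default 0.95.
#' @param nIter iterations per autosome; default 100.
#' @param masterSeed master seed.
#' @param population population label for the reconstructed panel.
#' @return list: \code{cohort} (\linkS4class{ReconstructedCohort}),
#'   \code{panel} (reconstructed \linkS4class{HaplotypePanel}, or
#'   \code{NULL} when no reconstruction is possible), \code{gaps},
#'   \code{perAutosome} (list of \linkS4class{IterationResult}).
#' @export
reconstructPopulation <- function(fragments, panel, spans = NULL,
                                  threshold = 0.95, nIter = 100L,
                                  masterSeed = 1L,
                                  population = "reconstructed") {
    if (is.null(spans)) spans <- panelSpans(panel)
    chroms <- unique(as.character(seqnames(fragments)))
    perAuto <- list()
    for (ai in seq_along(chroms)) {
        ch <- chroms[ai]
        perAuto[[ch]] <- bestIteration(
            fragments[as.character(seqnames(fragments)) == ch],
            spans[[ch]], threshold = threshold, nIter = nIter,
            masterSeed = mixSeed(masterSeed, 3L, ai))
    }
    cohort <- assemblePopulation(perAuto, seed = mixSeed(masterSeed, 4L),
                                 prefix = paste0(population, "_RI"))
    if (cohort@status != "ok")
        return(list(cohort = cohort, panel = NULL, gaps = NULL,
                    perAutosome = perAuto))
    mat <- materializeCohort(cohort, panel, population = population)
    list(cohort = cohort, panel = mat$panel, gaps = mat$gaps,
         perAutosome = perAuto)
}
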