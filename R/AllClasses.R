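#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
NULL

#' Phased haplotype panel
#'
#' A \code{HaplotypePanel} stores a phased, biallelic SNP panel as a
#' \linkS4class{RangedSummarizedExperiment}: one row per site, one column per
#' haplotype.  The single assay \code{"alleles"} is an integer matrix with
#' values 0 (reference), 1 (alternate) or \code{NA} (missing allele, i.e. a
#' half-call on one side of a phased genotype).  Row ranges carry the site
#' metadata (\code{ref}, \code{alt}, and optionally the genetic position
#' \code{cm}); column data carry \code{sample_id}, \code{side} (0 or 1) and
#' optionally \code{population}.
#'
#' Invariants enforced by the validity method: sites are strictly increasing
#' in position within each chromosome; every sample contributes exactly two
#' haplotypes (sides 0 and 1); alleles are coded in \{0, 1, NA\}.
#'
#' @seealso [HaplotypePanel()] for construction, [readPhasedVcf()] /
#'   [writePhasedVcf()] for I/O.
#' @exportClass HaplotypePanel
setClass("HaplotypePanel", contains = "RangedSummarizedExperiment")

setValidity("HaplotypePanel", function(object) {
    msg <- character()
    if (!"alleles" %in% SummarizedExperiment::assayNames(object))
        return("assay 'alleles' is required")
    a <- SummarizedExperiment::assay(object, "alleles")
    if (!all(a %in% c(0L, 1L, NA_integer_)))
        msg <- c(msg, "alleles must be 0, 1 or NA")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sample_id", "side") %in% colnames(cd)))
        return("colData must contain 'sample_id' and 'side'")
    if (ncol(object) > 0) {
        if (!all(cd$side %in% c(0L, 1L)))
            msg <- c(msg, "haplotype side must be 0 or 1")
        tab <- table(cd$sample_id)
        if (any(tab != 2L))
            msg <- c(msg, "each sample must contribute exactly two haplotypes")
        key <- paste(cd$sample_id, cd$side)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (sample, side) haplotype")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr) > 1) {
        bychrom <- split(GenomicRanges::start(rr),
                         as.character(GenomicRanges::seqnames(rr)))
        if (!all(vapply(bychrom, function(p) all(diff(p) > 0), logical(1))))
            msg <- c(msg, "site positions must be strictly increasing per chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Genetic map
#'
#' Per-chromosome anchor lists of (physical position, genetic position)
#' pairs.  Anchors are strictly increasing in base pairs and non-decreasing
#' in centimorgans; genetic positions between anchors are obtained by linear
#' interpolation and positions outside the anchored range clamp to the
#' boundary value (see [interpolateCm()]).
#'
#' @slot anchors a \code{data.frame} with columns \code{chrom},
#'   \code{pos_bp}, \code{cm}.
#' @exportClass GeneticMap
setClass("GeneticMap", representation(anchors = "data.frame"))

setValidity("GeneticMap", function(object) {
    a <- object@anchors
    if (!all(c("chrom", "pos_bp", "cm") %in% colnames(a)))
        return("anchors need columns chrom, pos_bp, cm")
    for (ch in unique(a$chrom)) {
        sub <- a[a$chrom == ch, ]
        if (nrow(sub) < 2)
            return(sprintf("chromosome %s has fewer than two anchors", ch))
        if (any(diff(sub$pos_bp) <= 0))
            return(sprintf("anchors not strictly increasing in pos_bp on %s", ch))
        if (any(diff(sub$cm) < 0))
            return(sprintf("anchors decreasing in cm on %s", ch))
    }
    TRUE
})

#' A rearranged (reconstructed) chromosome
#'
#' One non-overlapping, left-to-right placement of target-ancestry fragments
#' on an autosome.  Gaps between placed fragments are treated as missing
#' sequence; \code{coverage} is the fraction of the chromosome span covered
#' by placements (integer base-pair arithmetic, placements clipped to the
#' span).
#'
#' @slot chrom chromosome label.
#' @slot placements \code{GRanges} of placed fragments, sorted by start, with
#'   metadata columns \code{fragment_id}, \code{source_sample},
#'   \code{source_side}.
#' @slot gaps \code{GRanges} of missing intervals within the span.
#' @slot span integer of length 2: first and last base pair (1-based,
#'   inclusive) of the chromosome span used as coverage denominator.
#' @slot coverage numeric in [0, 1].
#' @slot retained logical: coverage at or above the retention threshold.
#' @exportClass RearrangedChromosome
setClass("RearrangedChromosome", representation(
    chrom = "character", placements = "GRanges", gaps = "GRanges",
    span = "integer", coverage = "numeric", retained = "logical"))

setValidity("RearrangedChromosome", function(object) {
    msg <- character()
    if (length(object@span) != 2L || object@span[1] > object@span[2])
        msg <- c(msg, "span must be (first_bp, last_bp) with first <= last")
    p <- object@placements
    if (length(p) > 1) {
        s <- GenomicRanges::start(p); e <- GenomicRanges::end(p)
        if (is.unsorted(s)) msg <- c(msg, "placements must be sorted by start")
        if (any(s[-1] <= e[-length(e)]))
            msg <- c(msg, "placement start must exceed previous placement end")
    }
    if (object@coverage < 0 || object@coverage > 1)
        msg <- c(msg, "coverage must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' One iteration of the jigsaw rearrangement
#'
#' The full set of rearranged chromosomes produced by one seeded pass of the
#' reconstruction over a fragment pool, together with the count retained at
#' the coverage threshold.  Every fragment is used at most once within an
#' iteration.
#'
#' @slot iteration zero-based iteration index.
#' @slot seed the derived seed this iteration ran under.
#' @slot chrom chromosome label.
#' @slot chromosomes list of \linkS4class{RearrangedChromosome}.
#' @slot threshold retention coverage threshold.
#' @slot nAboveThreshold number of chromosomes with coverage >= threshold.
#' @exportClass IterationResult
setClass("IterationResult", representation(
    iteration = "integer", seed = "numeric", chrom = "character",
    chromosomes = "list", threshold = "numeric", nAboveThreshold = "integer"))

setValidity("IterationResult", function(object) {
    ids <- unlist(lapply(object@chromosomes,
                         function(ch) ch@placements$fragment_id))
    if (anyDuplicated(ids))
        return("a fragment id appears in more than one chromosome")
    n <- sum(vapply(object@chromosomes, function(ch) ch@retained, logical(1)))
    if (n != object@nAboveThreshold)
        return("nAboveThreshold inconsistent with retained flags")
    TRUE
})

#' A reconstructed diploid individual
#'
#' One pair of rearranged chromosomes per autosome, with full fragment
#' provenance retained in the placements.
#'
#' @slot id individual identifier.
#' @slot chromosomes named list (by autosome); each element a list of two
#'   \linkS4class{RearrangedChromosome}.
#' @exportClass ReconstructedIndividual
setClass("ReconstructedIndividual", representation(
    id = "character", chromosomes = "list"))

setValidity("ReconstructedIndividual", function(object) {
    ok <- vapply(object@chromosomes, function(x)
        is.list(x) && length(x) == 2L &&
            all(vapply(x, is, logical(1), "RearrangedChromosome")), logical(1))
    if (!all(ok)) return("each autosome needs exactly two rearranged chromosomes")
    TRUE
})

#' A reconstructed cohort
#'
#' The outcome of pairing retained rearranged chromosomes across autosomes.
#' When any autosome retains no chromosome (or fewer than two), the cohort
#' carries the explicit status \code{"no reconstruction possible"} rather
#' than silently returning an empty list.
#'
#' @slot individuals list of \linkS4class{ReconstructedIndividual}.
#' @slot status \code{"ok"} or \code{"no reconstruction possible"}.
#' @slot nRetained named integer: retained chromosomes per autosome.
#' @exportClass ReconstructedCohort
setClass("ReconstructedCohort", representation(
    individuals = "list", status = "character", nRetained = "integer"))

#' Simulation configuration
#'
#' Parameters of the built-in admixture simulator: a single autosome of
#' \code{chromLengthBp} base pairs and \code{totalCm} centimorgans carrying
#' \code{nSites} biallelic SNPs; differentiated source panels drawn from a
#' Balding-Nichols model around shared base frequencies; admixed haplotypes
#' built as single-pulse ancestry mosaics with switch points at rate
#' \code{G} per Morgan and ancestry drawn independently from the admixture
#' proportions \code{alpha} of the haplotype's deme.
#'
#' @slot nSites number of segregating sites.
#' @slot chromLengthBp chromosome length in base pairs.
#' @slot totalCm chromosome genetic length in centimorgans.
#' @slot sources \code{data.frame} with columns \code{label}, \code{fst},
#'   \code{nHaplotypes}.
#' @slot alpha admixture-proportion matrix, one row per deme (rownames are
#'   deme labels), one column per source label; rows sum to 1.
#' @slot G generations since the admixture pulse.
#' @slot nAdmixed named integer: admixed diploids per deme.
#' @slot masterSeed integer master seed.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nSites = "integer", chromLengthBp = "integer", totalCm = "numeric",
    sources = "data.frame", alpha = "matrix", G = "numeric",
    nAdmixed = "integer", masterSeed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@G < 1) msg <- c(msg, "G must be >= 1")
    if (!all(c("label", "fst", "nHaplotypes") %in% colnames(object@sources)))
        msg <- c(msg, "sources needs columns label, fst, nHaplotypes")
    else if (any(object@sources$fst <= 0 | object@sources$fst >= 1))
        msg <- c(msg, "FST must lie in (0, 1)")
    al <- object@alpha
    if (!identical(sort(colnames(al)), sort(object@sources$label)))
        msg <- c(msg, "alpha columns must match source labels")
    if (any(al < 0) || any(abs(rowSums(al) - 1) > 1e-8))
        msg <- c(msg, "alpha rows must be non-negative and sum to 1")
    if (!identical(sort(names(object@nAdmixed)), sort(rownames(al))))
        msg <- c(msg, "nAdmixed names must match alpha deme rownames")
    if (length(msg)) msg else TRUE
})

setMethod("$", "SimConfig", function(x, name) slot(x, name))
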