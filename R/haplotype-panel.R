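#' Construct a HaplotypePanel
#'
#' @param alleles integer matrix, sites in rows, haplotypes in columns;
#'   values 0, 1 or \code{NA} (missing allele).
#' @param sites \code{data.frame} with columns \code{chrom}, \code{pos_bp},
#'   \code{ref}, \code{alt} and optionally \code{cm}.
#' @param sampleId character vector: owning sample of each haplotype column.
#' @param side integer vector of 0/1: which side of the phased genotype each
#'   haplotype column is.
#' @param population optional character vector or named map
#'   \code{sample_id -> population label}.
#' @return a \linkS4class{HaplotypePanel}.
#' @export
#' @examples
#' p <- HaplotypePanel(
#'   alleles = matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L), nrow = 2),
#'   sites = data.frame(chrom = "1", pos_bp = c(100L, 200L),
#'                      ref = "A", alt = "G"),
#'   sampleId = rep(c("s1", "s2"), each = 2), side = rep(0:1, 2))
#' altFreq(p)
HaplotypePanel <- function(alleles, sites, sampleId, side, population = NULL) {
    checkColumns(sites, c("chrom", "pos_bp", "ref", "alt"), "sites")
    alleles <- as.matrix(alleles)
    storage.mode(alleles) <- "integer"
    if (nrow(alleles) != nrow(sites))
        stopf("alleles has %d rows but sites %d", nrow(alleles), nrow(sites))
    if (ncol(alleles) != length(sampleId) || length(sampleId) != length(side))
        stopf("sampleId/side must match the number of haplotype columns")
    rr <- GRanges(as.character(sites$chrom),
                  IRanges(start = sites$pos_bp, width = 1L),
                  ref = as.character(sites$ref), alt = as.character(sites$alt),
                  cm = if ("cm" %in% colnames(sites)) as.numeric(sites$cm)
                       else rep(NA_real_, nrow(sites)))
    pop <- if (is.null(population)) rep(NA_character_, length(sampleId))
           else if (!is.null(names(population)))
               unname(population[as.character(sampleId)])
           else as.character(population)
    cd <- DataFrame(sample_id = as.character(sampleId),
                    side = as.integer(side), population = pop)
    colnames(alleles) <- rownames(cd) <- paste0(sampleId, "|", side)
    new("HaplotypePanel",
        SummarizedExperiment(assays = list(alleles = alleles),
                             rowRanges = rr, colData = cd))
}

#' Accessors for HaplotypePanel
#'
#' \code{alleles} returns the sites x haplotypes integer matrix;
#' \code{sampleIds} the unique sample identifiers; \code{haplotypeSample} /
#' \code{haplotypeSide} the per-column provenance; \code{populations} the
#' named \code{sample -> population} map; \code{altFreq} the per-site
#' alternate-allele frequency over non-missing alleles.
#'
#' @param x a \linkS4class{HaplotypePanel}.
#' @param value named character map \code{sample_id -> population}.
#' @return see the individual descriptions.
#' @name HaplotypePanel-accessors
#' @aliases alleles sampleIds haplotypeSample haplotypeSide populations
#'   populations<- altFreq
NULL

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("alleles", "HaplotypePanel", function(x) assay(x, "alleles"))

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("sampleIds", "HaplotypePanel",
          function(x) unique(colData(x)$sample_id))

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("haplotypeSample", "HaplotypePanel",
          function(x) colData(x)$sample_id)

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("haplotypeSide", "HaplotypePanel", function(x) colData(x)$side)

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("populations", "HaplotypePanel", function(x) {
    cd <- colData(x)
    pop <- cd$population[!duplicated(cd$sample_id)]
    names(pop) <- cd$sample_id[!duplicated(cd$sample_id)]
    pop
})

#' @rdname HaplotypePanel-accessors
#' @export
setReplaceMethod("populations", "HaplotypePanel", function(x, value) {
    cd <- colData(x)
    cd$population <- unname(value[as.character(cd$sample_id)])
    SummarizedExperiment::colData(x) <- cd
    validObject(x)
    x
})

#' @rdname HaplotypePanel-accessors
#' @export
setMethod("altFreq", "HaplotypePanel",
          function(x) rowMeans(assay(x, "alleles"), na.rm = TRUE))

setMethod("show", "HaplotypePanel", function(object) {
    cat(sprintf("HaplotypePanel: %d sites x %d haplotypes (%d samples)\n",
                nrow(object), ncol(object), length(sampleIds(object))))
    pop <- populations(object)
    if (any(!is.na(pop))) {
        tab <- table(pop, useNA = "no")
        cat("  populations:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    }
    miss <- mean(is.na(assay(object, "alleles")))
    cat(sprintf("  missing alleles: %.2f%%\n", 100 * miss))
})

#' Subset a panel to one population
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param pop population label.
#' @return the \linkS4class{HaplotypePanel} of that population's haplotypes.
#' @export
subsetPopulation <- function(panel, pop) {
    keep <- which(colData(panel)$population == pop)
    if (!length(keep)) stopf("no haplotypes in population '%s'", pop)
    panel[, keep]
}

#' Attach genetic-map positions to a panel
#'
#' Fills the per-site \code{cm} metadata by interpolating \code{map} at the
#' site positions.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param map a \linkS4class{GeneticMap}.
#' @return the panel with \code{cm} filled in.
#' @export
applyGeneticMap <- function(panel, map) {
    rr <- rowRanges(panel)
    chroms <- as.character(seqnames(rr))
    cm <- numeric(length(rr))
    for (ch in unique(chroms)) {
        i <- chroms == ch
        cm[i] <- interpolateCm(map, ch, GenomicRanges::start(rr)[i])
    }
    rr$cm <- cm
    SummarizedExperiment::rowRanges(panel) <- rr
    panel
}

## ---- VCF I/O ---------------------------------------------------------------

#' Read a phased VCF into a HaplotypePanel
#'
#' Retains biallelic SNP records with a phased diploid GT; multiallelic or
#' non-SNP records are skipped with a message reporting the count.  A "."
#' allele inside a phased genotype (half-call) becomes a missing allele on
#' that haplotype only.  Records with an unphased separator ("/"), a missing
#' GT FORMAT field, or ploidy other than 2 raise an error.
#'
#' @param path VCF file (plain or gzipped), VCF 4.x with GT.
#' @return a \linkS4class{HaplotypePanel} (two haplotypes per sample).
#' @seealso [writePhasedVcf()]
#' @export
readPhasedVcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    if (nrow(fix) == 0) {
        smp <- colnames(v@gt)[-1]
        if (is.null(smp)) smp <- character()
        return(HaplotypePanel(
            matrix(integer(), 0, 2 * length(smp)),
            data.frame(chrom = character(), pos_bp = integer(),
                       ref = character(), alt = character()),
            rep(smp, each = 2), rep(0:1, length(smp))))
    }
    gtfmt <- v@gt[, "FORMAT"]
    if (any(!vapply(strsplit(gtfmt, ":", fixed = TRUE),
                    function(f) "GT" %in% f, logical(1))))
        stopf("VCF record without GT in FORMAT")
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    biallelic <- !grepl(",", alt, fixed = TRUE) &
        nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
    nskip <- sum(!biallelic)
    if (nskip > 0)
        message(sprintf("readPhasedVcf: skipped %d multiallelic/non-SNP record(s)",
                        nskip))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[biallelic, , drop = FALSE]
    fix <- fix[biallelic, , drop = FALSE]
    smp <- colnames(gt)
    nsite <- nrow(gt)
    al <- matrix(NA_integer_, nsite, 2L * length(smp))
    for (j in seq_along(smp)) {
        g <- gt[, j]
        g[is.na(g)] <- ".|."   # fully missing genotypes parse as NA
        if (any(grepl("/", g, fixed = TRUE)))
            stopf("unphased genotype for sample %s", smp[j])
        parts <- strsplit(g, "|", fixed = TRUE)
        len <- lengths(parts)
        if (nsite > 0 && any(len != 2L))
            stopf("non-diploid genotype for sample %s", smp[j])
        m <- matrix(unlist(parts), nrow = 2L)
        for (k in 1:2) {
            a <- m[k, ]
            a[a == "."] <- NA
            if (any(!a %in% c("0", "1", NA)))
                stopf("unexpected allele code in sample %s", smp[j])
            al[, 2L * (j - 1L) + k] <- as.integer(a)
        }
    }
    HaplotypePanel(
        al,
        data.frame(chrom = fix[, "CHROM"], pos_bp = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = fix[, "ALT"]),
        rep(smp, each = 2), rep(0:1, length(smp)))
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Writes VCF 4.2 with phased GT; missing alleles are written as "." on
#' their side of the genotype (the half-call dialect, e.g. \code{"0|."}).
#' Round-trips through [readPhasedVcf()] on alleles, missingness, sample ids
#' and site order.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
    validObject(panel)
    smp <- sampleIds(panel)
    hs <- haplotypeSample(panel); sd <- haplotypeSide(panel)
    a <- assay(panel, "alleles")
    ach <- matrix(as.character(a), nrow = nrow(a))
    ach[is.na(ach)] <- "."
    cols <- lapply(smp, function(s) {
        i0 <- which(hs == s & sd == 0L); i1 <- which(hs == s & sd == 1L)
        if (nrow(ach) == 0) character() else
            paste(ach[, i0], ach[, i1], sep = "|")
    })
    rr <- rowRanges(panel)
    body <- if (length(rr) == 0) character() else do.call(paste, c(list(
        as.character(seqnames(rr)), GenomicRanges::start(rr),
        ".", rr$ref, rr$alt, ".", "PASS", ".", "GT"), cols, list(sep = "\t")))
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=AncestryJigsaw",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype; '.' denotes a missing allele (half-call)\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", smp), collapse = "\t"))
    writeLines(c(header, body), path)
    invisible(path)
}
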