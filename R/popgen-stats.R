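#' f-statistic result
#'
#' Estimate, weighted block-jackknife standard error, Z score and block
#' count for an f3 or f4 statistic.
#'
#' @slot estimate the plain mean-over-sites estimate.
#' @slot se leave-one-block-out jackknife standard error.
#' @slot z \code{estimate / se} (0 when the statistic is identically 0).
#' @slot nBlocks number of jackknife blocks.
#' @slot nSites number of sites contributing.
#' @exportClass FStatResult
setClass("FStatResult", representation(
    estimate = "numeric", se = "numeric", z = "numeric",
    nBlocks = "integer", nSites = "integer"))

setMethod("show", "FStatResult", function(object) {
    cat(sprintf("f-statistic: %.6g  SE %.3g  Z %.3f  (%d blocks, %d sites)\n",
                object@estimate, object@se, object@z, object@nBlocks,
                object@nSites))
})

#' Per-site nucleotide diversity
#'
#' The per-SNP diversity reported by \code{vcftools --site-pi}: with n
#' non-missing alleles of which c are alternate, pi = 2 c (n - c) /
#' (n (n - 1)).  Missing alleles are excluded from n; sites with fewer than
#' two observed alleles are skipped (NA).
#'
#' @param panel a \linkS4class{HaplotypePanel} (typically one population's
#'   haplotypes, see [subsetPopulation()]).
#' @return \code{data.frame} with columns \code{CHROM}, \code{POS},
#'   \code{PI} (NA where skipped).
#' @export
sitePi <- function(panel) {
    a <- assay(panel, "alleles")
    n <- rowSums(!is.na(a))
    c1 <- rowSums(a == 1L, na.rm = TRUE)
    pi <- ifelse(n >= 2, 2 * c1 * (n - c1) / (n * (n - 1)), NA_real_)
    rr <- rowRanges(panel)
    data.frame(CHROM = as.character(seqnames(rr)),
               POS = GenomicRanges::start(rr), PI = pi)
}

## weighted delete-one-block jackknife (unequal block sizes); returns SE
blockJackknifeSE <- function(terms, blockId) {
    ok <- !is.na(terms)
    terms <- terms[ok]; blockId <- blockId[ok]
    n <- length(terms)
    blocks <- unique(blockId)
    B <- length(blocks)
    if (B < 2) stopf("need at least two jackknife blocks with data")
    tot <- sum(terms)
    sumj <- vapply(split(terms, blockId), sum, numeric(1))
    mj <- vapply(split(terms, blockId), length, numeric(1))
    theta <- tot / n
    thetaMinus <- (tot - sumj) / (n - mj)
    h <- n / mj
    thetaJ <- B * theta - sum((1 - mj / n) * thetaMinus)
    tau <- h * theta - (h - 1) * thetaMinus
    varJ <- mean((tau - thetaJ)^2 / (h - 1))
    list(se = sqrt(varJ), nBlocks = as.integer(B), nSites = as.integer(n))
}

## shared machinery: per-population alt frequencies + site filter + blocks
fStatCore <- function(panels, termFun, blockSizeCm) {
    pos <- GenomicRanges::start(rowRanges(panels[[1]]))
    for (p in panels[-1]) {
        if (nrow(p) != length(pos) ||
            any(GenomicRanges::start(rowRanges(p)) != pos))
            stopf("panels must share an identical site set")
        if (ncol(p) == 0) stopf("a population has zero haplotypes")
    }
    if (ncol(panels[[1]]) == 0) stopf("a population has zero haplotypes")
    freqs <- lapply(panels, altFreq)
    counts <- lapply(panels, function(p)
        rowSums(!is.na(assay(p, "alleles"))))
    ok <- Reduce(`&`, lapply(counts, function(x) x > 0))
    terms <- termFun(freqs)
    terms[!ok] <- NA
    cm <- rowRanges(panels[[1]])$cm
    if (all(is.na(cm))) stopf("sites carry no genetic (cM) positions; apply a map")
    blockId <- paste(as.character(seqnames(rowRanges(panels[[1]]))),
                     floor(cm / blockSizeCm))
    est <- mean(terms, na.rm = TRUE)
    jk <- blockJackknifeSE(terms, blockId)
    z <- if (jk$se > 0) est / jk$se else if (est == 0) 0 else sign(est) * Inf
    new("FStatResult", estimate = est, se = jk$se, z = z,
        nBlocks = jk$nBlocks, nSites = jk$nSites)
}

#' f4 statistic with weighted block jackknife
#'
#' f4(A, B; C, D) is the mean over sites of (pA - pB)(pC - pD), with
#' allele frequencies computed from non-missing alleles; sites where any
#' population is fully missing are skipped.  The standard error comes from
#' a leave-one-block-out jackknife over genetic-map blocks of
#' \code{blockSizeCm} centimorgans, weighted by block size.  Under
#' treeness ((A,B) against (C,D)) the expectation is zero, so |Z| measures
#' evidence of gene flow / residual shared ancestry.
#'
#' @param panelA,panelB,panelC,panelD \linkS4class{HaplotypePanel}s over an
#'   identical site set, with cM positions attached.
#' @param blockSizeCm jackknife block size in cM; default 0.5 (suited to
#'   the simulator's 1-Morgan scale; use larger blocks on genome data).
#' @return an \linkS4class{FStatResult}.
#' @export
f4 <- function(panelA, panelB, panelC, panelD, blockSizeCm = 0.5) {
    fStatCore(list(panelA, panelB, panelC, panelD),
              function(f) (f[[1]] - f[[2]]) * (f[[3]] - f[[4]]),
              blockSizeCm)
}

#' Outgroup f3 statistic with weighted block jackknife
#'
#' f3(T; A, B) is the mean over sites of (pT - pA)(pT - pB), measuring the
#' shared drift of A and B relative to T (the outgroup when T is an
#' outgroup).  Same site filtering and jackknife as [f4()].
#'
#' @param panelT,panelA,panelB \linkS4class{HaplotypePanel}s over an
#'   identical site set.
#' @param blockSizeCm jackknife block size in cM; default 0.5.
#' @return an \linkS4class{FStatResult}.
#' @export
f3 <- function(panelT, panelA, panelB, blockSizeCm = 0.5) {
    fStatCore(list(panelT, panelA, panelB),
              function(f) (f[[1]] - f[[2]]) * (f[[1]] - f[[3]]),
              blockSizeCm)
}

#' Residual-ancestry check via f4
#'
#' Tests whether reconstructed individuals retain ancestry from the
#' distractor (non-target) sources: f4(reconstructed, target source;
#' distractor1, distractor2).  With a clean reconstruction the
#' reconstructed panel behaves as a sister of the target source and the
#' statistic is consistent with zero; |Z| < 4 is the "no residual
#' ancestry" verdict.
#'
#' @param reconstructed reconstructed \linkS4class{HaplotypePanel}.
#' @param targetPanel target-ancestry source panel.
#' @param distractor1,distractor2 distractor source panels.
#' @param blockSizeCm jackknife block size in cM; default 0.5.
#' @return an \linkS4class{FStatResult}.
#' @export
residualAncestryCheck <- function(reconstructed, targetPanel, distractor1,
                                  distractor2, blockSizeCm = 0.5) {
    f4(reconstructed, targetPanel, distractor1, distractor2, blockSizeCm)
}

#' Donor totals by minimum-mismatch window painting
#'
#' A deliberately simple haplotype-painting surrogate (not a Li & Stephens
#' copying model): each recipient haplotype is cut into consecutive windows
#' of \code{windowSites} sites; each window is assigned to the donor
#' population containing a minimum-Hamming-distance haplotype (missing
#' recipient sites are excluded from the comparison; ties split the window
#' equally among tied donors); window lengths are measured in cM and
#' totals are summed per recipient individual.  Downstream comparisons rely
#' only on rank/direction properties, which are robust to this
#' approximation.
#'
#' @param recipients recipient \linkS4class{HaplotypePanel}.
#' @param donors named list of donor \linkS4class{HaplotypePanel}s over the
#'   same site set.
#' @param windowSites sites per painting window (>= 10); default 50.
#' @return numeric matrix: recipient individuals x donor populations, total
#'   copied length in cM.  Row sums equal the painted genome length.
#' @export
windowPainting <- function(recipients, donors, windowSites = 50L) {
    if (windowSites < 10) stopf("windowSites must be >= 10")
    if (is.null(names(donors)) || any(names(donors) == ""))
        stopf("donors must be a named list")
    rr <- rowRanges(recipients)
    pos <- GenomicRanges::start(rr)
    cm <- rr$cm
    if (all(is.na(cm))) stopf("recipient sites carry no cM positions")
    chrom <- as.character(seqnames(rr))
    for (d in donors)
        if (nrow(d) != length(pos) ||
            any(GenomicRanges::start(rowRanges(d)) != pos))
            stopf("donor panels must share the recipients' site set")
    ## window cM length from midpoint boundaries so rows sum to the full
    ## painted span regardless of windowSites
    nsite <- length(pos)
    bounds <- c(cm[1], (cm[-1] + cm[-nsite]) / 2, cm[nsite])
    donorsA <- lapply(donors, function(d) assay(d, "alleles"))
    recA <- assay(recipients, "alleles")
    hs <- haplotypeSample(recipients)
    inds <- sampleIds(recipients)
    totals <- matrix(0, length(inds), length(donors),
                     dimnames = list(inds, names(donors)))
    ## windows never span a chromosome boundary
    winOf <- unlist(lapply(split(seq_len(nsite), chrom)[unique(chrom)],
        function(i) paste(chrom[i[1]],
                          (seq_along(i) - 1L) %/% windowSites)))
    winIdx <- split(seq_len(nsite), winOf)
    for (h in seq_len(ncol(recA))) {
        r <- recA[, h]
        indRow <- match(hs[h], inds)
        for (w in winIdx) {
            ok <- w[!is.na(r[w])]
            if (!length(ok)) next
            rv <- r[ok]
            mism <- vapply(donorsA, function(D)
                min(colSums(abs(D[ok, , drop = FALSE] - rv))),
                numeric(1))
            best <- which(mism == min(mism))
            wlen <- bounds[max(w) + 1] - bounds[min(w)]
            totals[indRow, best] <- totals[indRow, best] +
                wlen / length(best)
        }
    }
    totals
}

#' Pairwise differential-ancestry comparison of donor totals
#'
#' For each donor population and each unordered pair of recipient groups,
#' a two-sided Wilcoxon rank-sum test compares the distributions of total
#' copied length; p-values are Bonferroni-corrected over all performed
#' (donor x pair) tests, and a comparison is flagged significant when the
#' corrected p-value is below \code{alpha} (default 0.005).  Groups with
#' fewer than 3 members are skipped with a warning.
#'
#' @param totals donor-totals matrix from [windowPainting()].
#' @param groups named map: recipient individual -> group label.
#' @param alpha corrected-p significance cutoff; default 0.005.
#' @return \code{data.frame} with one row per (donor, pair): \code{donor},
#'   \code{group1}, \code{group2}, \code{n1}, \code{n2}, \code{p},
#'   \code{p_bonferroni}, \code{direction} (group with the larger mean),
#'   \code{significant}.
#' @export
differentialAncestryTest <- function(totals, groups, alpha = 0.005) {
    g <- unname(groups[rownames(totals)])
    if (anyNA(g)) stopf("every recipient needs a group label")
    glabs <- sort(unique(g))
    if (length(glabs) < 2) stopf("need at least two groups")
    pairs <- utils::combn(glabs, 2, simplify = FALSE)
    rows <- list()
    for (donor in colnames(totals)) for (pr in pairs) {
        x <- totals[g == pr[1], donor]; y <- totals[g == pr[2], donor]
        if (length(x) < 3 || length(y) < 3) {
            warning(sprintf("pair (%s, %s) skipped: group with < 3 members",
                            pr[1], pr[2]))
            next
        }
        wt <- suppressWarnings(stats::wilcox.test(x, y))
        rows[[length(rows) + 1L]] <- data.frame(
            donor = donor, group1 = pr[1], group2 = pr[2],
            n1 = length(x), n2 = length(y), p = wt$p.value,
            direction = if (mean(x) >= mean(y)) pr[1] else pr[2])
    }
    if (!length(rows))
        return(data.frame(donor = character(), group1 = character(),
                          group2 = character(), n1 = integer(),
                          n2 = integer(), p = numeric(),
                          p_bonferroni = numeric(),
                          direction = character(),
                          significant = logical()))
    res <- do.call(rbind, rows)
    res$p_bonferroni <- stats::p.adjust(res$p, method = "bonferroni")
    res$significant <- res$p_bonferroni < alpha
    res[c("donor", "group1", "group2", "n1", "n2", "p", "p_bonferroni",
          "direction", "significant")]
}
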