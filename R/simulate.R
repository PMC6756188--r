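#' Construct a simulation configuration
#'
#' Defaults emulate the admixed-cohort setting the reconstruction method is
#' designed for, at desk scale: one chromosome of 1 Morgan carrying 2,000
#' array-like SNPs; three continental source populations differentiated at
#' FST 0.1 from a shared ancestral frequency; a single admixture pulse
#' \code{G = 20} generations ago; and a low target-ancestry proportion (7%
#' on average) with the remainder split between the two distractor
#' ancestries.
#'
#' @param nSites number of biallelic sites (default 2000).
#' @param chromLengthBp chromosome length in bp (default 1e8).
#' @param totalCm genetic length in cM (default 100, i.e. 1 Morgan).
#' @param sources \code{data.frame(label, fst, nHaplotypes)}; panel sizes
#'   must be even (diploid samples).
#' @param alpha admixture proportions: matrix demes x sources (rows sum to
#'   1), or a named vector for a single deme.
#' @param G generations since the admixture pulse (default 20).
#' @param nAdmixed named integer, admixed diploids per deme (default 200).
#' @param masterSeed master seed (default 1).
#' @return a \linkS4class{SimConfig}.
#' @export
#' @examples
#' cfg <- SimConfig(nAdmixed = c(deme1 = 50))
SimConfig <- function(nSites = 2000L, chromLengthBp = 1e8, totalCm = 100,
                      sources = data.frame(
                          label = c("NAT", "EUR", "AFR"),
                          fst = c(0.1, 0.1, 0.1),
                          nHaplotypes = c(40L, 40L, 40L)),
                      alpha = c(NAT = 0.07, EUR = 0.55, AFR = 0.38),
                      G = 20, nAdmixed = c(deme1 = 200L),
                      masterSeed = 1L) {
    if (is.null(dim(alpha))) {
        alpha <- matrix(alpha, nrow = length(nAdmixed),
                        ncol = length(alpha), byrow = TRUE,
                        dimnames = list(names(nAdmixed), names(alpha)))
    }
    if (any(sources$nHaplotypes %% 2L != 0L))
        stopf("source panel sizes must be even (diploid samples)")
    new("SimConfig", nSites = as.integer(nSites),
        chromLengthBp = as.integer(chromLengthBp),
        totalCm = as.numeric(totalCm),
        sources = as.data.frame(sources), alpha = alpha,
        G = as.numeric(G),
        nAdmixed = stats::setNames(as.integer(nAdmixed), names(nAdmixed)),
        masterSeed = as.numeric(masterSeed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d sites, %.0f bp / %.0f cM, G = %.0f, seed %d\n",
        object@nSites, as.numeric(object@chromLengthBp), object@totalCm,
        object@G, as.integer(object@masterSeed)))
    cat("  sources:", paste(sprintf("%s(FST %.3g, %d hap)",
        object@sources$label, object@sources$fst,
        object@sources$nHaplotypes), collapse = ", "), "\n")
    for (d in rownames(object@alpha))
        cat(sprintf("  deme %s: n = %d, alpha = (%s)\n", d,
                    object@nAdmixed[d],
                    paste(sprintf("%s %.2f", colnames(object@alpha),
                                  object@alpha[d, ]), collapse = ", ")))
})

#' Simulate differentiated source panels
#'
#' Base allele frequencies are drawn uniformly on (0.05, 0.95); each
#' source's per-site frequency is drawn from the Balding-Nichols
#' distribution \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} with that source's FST;
#' panel haplotypes are drawn independently per site from the source
#' frequencies.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list: \code{panels} (named list of \linkS4class{HaplotypePanel},
#'   one per source, population labels set), \code{baseFreq},
#'   \code{sourceFreq} (sites x sources), \code{map} (uniform-rate
#'   \linkS4class{GeneticMap}), \code{sites} (site \code{data.frame}),
#'   \code{chrom}.
#' @export
simulateSourcePanels <- function(config) {
    chrom <- "1"
    map <- uniformGeneticMap(chrom, config@chromLengthBp, config@totalCm)
    out <- withSeed(mixSeed(config@masterSeed, 11L), {
        pos <- sort(sample.int(config@chromLengthBp, config@nSites))
        p <- stats::runif(config@nSites, 0.05, 0.95)
        sites <- data.frame(chrom = chrom, pos_bp = pos,
                            ref = "A", alt = "G",
                            cm = interpolateCm(map, chrom, pos))
        srcFreq <- sapply(seq_len(nrow(config@sources)), function(si) {
            f <- config@sources$fst[si]
            stats::rbeta(config@nSites, p * (1 - f) / f,
                         (1 - p) * (1 - f) / f)
        })
        colnames(srcFreq) <- config@sources$label
        panels <- lapply(seq_len(nrow(config@sources)), function(si) {
            lab <- config@sources$label[si]
            nh <- config@sources$nHaplotypes[si]
            al <- matrix(stats::rbinom(config@nSites * nh, 1L,
                                       rep(srcFreq[, lab], nh)),
                         nrow = config@nSites)
            ns <- nh %/% 2L
            ids <- sprintf("%s_s%03d", lab, seq_len(ns))
            HaplotypePanel(al, sites, rep(ids, each = 2),
                           rep(0:1, ns),
                           population = rep(lab, nh))
        })
        names(panels) <- config@sources$label
        list(panels = panels, baseFreq = p, sourceFreq = srcFreq,
             sites = sites)
    })
    c(out, list(map = map, chrom = chrom))
}

#' Simulate an admixed cohort with ground-truth ancestry tracts
#'
#' Each admixed haplotype is a single-pulse ancestry mosaic: switch points
#' are placed by a Poisson process of rate \code{G} per Morgan along the
#' genetic map; the ancestry at the left end and after every switch is
#' drawn independently from the deme's admixture proportions; within each
#' tract, alleles are copied from one uniformly chosen donor haplotype of
#' that source's panel.  Switches that redraw the same ancestry are
#' invisible in the truth (recorded as separate segments, since the donor
#' haplotype changes).
#'
#' @param sim output of [simulateSourcePanels()].
#' @param config the same \linkS4class{SimConfig}.
#' @return list: \code{panel} (admixed \linkS4class{HaplotypePanel},
#'   population = deme label), \code{truth} (\code{data.frame} with columns
#'   \code{sample_id}, \code{side}, \code{deme}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{source}, \code{donor_hap}).
#' @export
simulateAdmixedCohort <- function(sim, config) {
    labs <- colnames(config@alpha)
    if (!all(labs %in% names(sim$panels)))
        stopf("alpha names a source with no simulated panel")
    chrom <- sim$chrom
    L <- config@totalCm / 100
    map <- sim$map
    donorAlleles <- lapply(sim$panels, function(p) assay(p, "alleles"))
    donorNames <- lapply(sim$panels, function(p) colnames(assay(p, "alleles")))
    nsite <- config@nSites
    pos <- sim$sites$pos_bp
    withSeed(mixSeed(config@masterSeed, 12L), {
        rows <- list()
        cols <- list()
        sampleId <- character(); side <- integer(); demeOf <- character()
        for (deme in rownames(config@alpha)) {
            al <- config@alpha[deme, labs]
            for (i in seq_len(config@nAdmixed[deme])) {
                sid <- sprintf("%s_a%04d", deme, i)
                for (sd in 0:1) {
                    nSw <- stats::rpois(1, config@G * L)
                    cuts <- sort(stats::runif(nSw, 0, config@totalCm))
                    edgesCm <- c(0, cuts, config@totalCm)
                    src <- sample(labs, nSw + 1L, replace = TRUE, prob = al)
                    bp <- round(interpolateBp(map, chrom, edgesCm))
                    bp[1] <- 0; bp[length(bp)] <- config@chromLengthBp
                    segS <- bp[-length(bp)] + 1
                    segE <- bp[-1]
                    ok <- segE >= segS
                    segS <- segS[ok]; segE <- segE[ok]; src <- src[ok]
                    donor <- vapply(src, function(s)
                        sample(donorNames[[s]], 1L), character(1))
                    hap <- rep(NA_integer_, nsite)
                    i1 <- findInterval(segS - 1, pos) + 1L
                    i2 <- findInterval(segE, pos)
                    for (k in seq_along(segS)) {
                        if (i2[k] >= i1[k])
                            hap[i1[k]:i2[k]] <-
                                donorAlleles[[src[k]]][i1[k]:i2[k], donor[k]]
                    }
                    cols[[length(cols) + 1L]] <- hap
                    sampleId <- c(sampleId, sid); side <- c(side, sd)
                    demeOf <- c(demeOf, deme)
                    rows[[length(rows) + 1L]] <- data.frame(
                        sample_id = sid, side = sd, deme = deme,
                        chrom = chrom, start_bp = segS, end_bp = segE,
                        source = src, donor_hap = donor)
                }
            }
        }
        truth <- do.call(rbind, rows)
        rownames(truth) <- NULL
        panel <- HaplotypePanel(
            do.call(cbind, cols), sim$sites, sampleId, side,
            population = demeOf)
        list(panel = panel, truth = truth)
    })
}

#' Summaries of simulator ground truth
#'
#' Per haplotype: the genome fraction of each source ancestry and the
#' number of visible ancestry switches (consecutive truth segments whose
#' source differs).
#'
#' @param truth truth \code{data.frame} from [simulateAdmixedCohort()].
#' @return \code{data.frame} with one row per haplotype: \code{sample_id},
#'   \code{side}, \code{deme}, \code{n_switches}, then one fraction column
#'   per source label.
#' @export
truthSummary <- function(truth) {
    key <- paste(truth$sample_id, truth$side)
    labs <- sort(unique(truth$source))
    len <- truth$end_bp - truth$start_bp + 1
    tot <- tapply(len, key, sum)
    keys <- names(tot)
    out <- data.frame(
        sample_id = sub(" [01]$", "", keys),
        side = as.integer(sub("^.* ", "", keys)),
        deme = truth$deme[match(keys, key)],
        n_switches = as.integer(tapply(seq_along(key), key, function(i) {
            s <- truth$source[i][order(truth$start_bp[i])]
            sum(s[-1] != s[-length(s)])
        })[keys]))
    for (lab in labs)
        out[[lab]] <- as.numeric(tapply(
            len * (truth$source == lab), key, sum)[keys]) / as.numeric(tot)
    rownames(out) <- NULL
    out
}

#' Convert truth segments to window-level local-ancestry calls
#'
#' Windows tile the chromosome at \code{windowCm} (default 0.2 cM, the
#' RFMix-style window size); each window is assigned the ancestry covering
#' the majority of its base pairs on that haplotype, with posterior mass 1.
#' Two corruption knobs support robustness and positive-control tests:
#' \code{eps} softens every posterior vector to \code{1 - eps} on the true
#' ancestry and \code{eps/(k-1)} on the others; \code{contamination}
#' relabels a random subset of non-target windows as the target ancestry
#' (posterior 1) so that the expected share of contaminant windows among
#' all target-labelled windows equals \code{contamination}.
#'
#' @param truth truth \code{data.frame} from [simulateAdmixedCohort()].
#' @param map a \linkS4class{GeneticMap}.
#' @param chromLengthBp chromosome length in bp.
#' @param windowCm window size in cM; default 0.2.
#' @param groups optional named map source label -> ancestry label, used to
#'   pool differentiated source populations into one called ancestry (e.g.
#'   two target-ancestry sources called as a single target).
#' @param eps symmetric posterior softening in [0, 1); default 0.
#' @param contamination target-contamination rate in [0, 1); default 0.
#' @param target ancestry label to contaminate (required when
#'   \code{contamination > 0}).
#' @param contaminateFrom restrict contaminant windows to this (called)
#'   ancestry; by default any non-target window is eligible.  A
#'   single-source contamination is the sharper positive control for the
#'   residual-ancestry f4, whose expectation cancels under perfectly
#'   symmetric two-source contamination.
#' @param seed seed for the contamination draw.
#' @param labels ancestry label set of the emitted posterior columns;
#'   defaults to the (grouped) source labels present in \code{truth}.
#' @return window calls \code{GRanges} (see [windowCalls()]).
#' @export
truthToWindowCalls <- function(truth, map, chromLengthBp, windowCm = 0.2,
                               groups = NULL, eps = 0, contamination = 0,
                               target = NULL, contaminateFrom = NULL,
                               seed = 1L, labels = NULL) {
    chrom <- truth$chrom[1]
    src <- truth$source
    if (!is.null(groups)) src <- unname(groups[src])
    labs <- if (is.null(labels)) sort(unique(src)) else labels
    a <- map@anchors[map@anchors$chrom == chrom, ]
    totalCm <- max(a$cm)
    edgesCm <- seq(0, totalCm, by = windowCm)
    if (edgesCm[length(edgesCm)] < totalCm) edgesCm <- c(edgesCm, totalCm)
    edges <- round(interpolateBp(map, chrom, edgesCm))
    edges[1] <- 0; edges[length(edges)] <- chromLengthBp
    edges <- unique(edges)
    nwin <- length(edges) - 1L
    wstart <- edges[-length(edges)] + 1
    wend <- edges[-1]
    key <- paste(truth$sample_id, truth$side)
    idxList <- split(seq_len(nrow(truth)), key)
    out <- vector("list", length(idxList))
    ki <- 0L
    for (i in idxList) {
        i <- i[order(truth$start_bp[i])]
        bpByAnc <- matrix(0, nwin, length(labs),
                          dimnames = list(NULL, labs))
        for (r in i) {
            s <- truth$start_bp[r]; e <- truth$end_bp[r]
            w1 <- findInterval(s, wstart)
            w2 <- findInterval(e, wstart)
            ww <- w1:w2
            ov <- pmin(e, wend[ww]) - pmax(s, wstart[ww]) + 1
            bpByAnc[ww, src[r]] <- bpByAnc[ww, src[r]] + ov
        }
        maj <- labs[max.col(bpByAnc, ties.method = "first")]
        ki <- ki + 1L
        out[[ki]] <- data.frame(
            chrom = chrom, start_bp = wstart, end_bp = wend,
            sample_id = truth$sample_id[i[1]], side = truth$side[i[1]],
            anc = maj)
    }
    df <- do.call(rbind, out)
    if (contamination > 0) {
        if (is.null(target)) stopf("contamination > 0 requires a target label")
        isT <- df$anc == target
        eligible <- if (is.null(contaminateFrom)) which(!isT)
                    else which(df$anc == contaminateFrom)
        if (!length(eligible)) stopf("no windows eligible for contamination")
        nT <- sum(isT); nO <- length(eligible)
        q <- min(1, contamination * nT / ((1 - contamination) * nO))
        flip <- withSeed(mixSeed(seed, 77L),
                         eligible[stats::runif(nO) < q])
        df$anc[flip] <- target
    }
    post <- matrix(eps / (length(labs) - 1), nrow(df), length(labs),
                   dimnames = list(NULL, labs))
    post[cbind(seq_len(nrow(df)), match(df$anc, labs))] <- 1 - eps
    res <- df[c("chrom", "start_bp", "end_bp", "sample_id", "side")]
    for (lab in labs) res[[lab]] <- post[, lab]
    windowCalls(res)
}

#' Differential-ancestry scenario fixture
#'
#' Builds the two-deme design used to exercise the donor-sharing
#' comparison: two differentiated target-ancestry source populations (J and
#' T) plus two distractor sources; deme A draws its target ancestry 80/20
#' from (J, T) and deme B 20/80 (or 50/50 in the symmetric null variant).
#' Both target sources are pooled into a single called target ancestry in
#' the emitted window calls, mirroring a three-way local-ancestry analysis
#' over a substructured target component.
#'
#' @param nAdmixed admixed diploids per deme; default 200.
#' @param alphaTarget total target-ancestry proportion per deme; default
#'   0.4.
#' @param jShare vector of length 2: share of the target ancestry drawn
#'   from source J in demes A and B; default \code{c(0.8, 0.2)}.
#' @param targetFst Balding-Nichols FST of each target source; default
#'   0.025 (the two target sources sit about 0.05 apart).
#' @param nSites number of sites; default 2000.
#' @param seed master seed.
#' @return list: \code{config}, \code{sim} (source panels and map),
#'   \code{cohort} (admixed panel + truth), \code{calls} (window calls with
#'   the pooled target label \code{"NAT"}), \code{groups} (source ->
#'   called-ancestry map), \code{expected} (deme with the larger J donor
#'   share, \code{"A"} under the default design, \code{NA} under the
#'   symmetric null).
#' @export
scenarioDifferential <- function(nAdmixed = 200L, alphaTarget = 0.4,
                                 jShare = c(0.8, 0.2), targetFst = 0.025,
                                 nSites = 2000L, seed = 1L) {
    rest <- (1 - alphaTarget) / 2
    alpha <- rbind(
        A = c(J = alphaTarget * jShare[1], T = alphaTarget * (1 - jShare[1]),
              EUR = rest, AFR = rest),
        B = c(J = alphaTarget * jShare[2], T = alphaTarget * (1 - jShare[2]),
              EUR = rest, AFR = rest))
    config <- SimConfig(
        nSites = nSites,
        sources = data.frame(label = c("J", "T", "EUR", "AFR"),
                             fst = c(targetFst, targetFst, 0.1, 0.1),
                             nHaplotypes = c(40L, 40L, 40L, 40L)),
        alpha = alpha, G = 20,
        nAdmixed = c(A = as.integer(nAdmixed), B = as.integer(nAdmixed)),
        masterSeed = seed)
    sim <- simulateSourcePanels(config)
    cohort <- simulateAdmixedCohort(sim, config)
    groups <- c(J = "NAT", T = "NAT", EUR = "EUR", AFR = "AFR")
    calls <- truthToWindowCalls(cohort$truth, sim$map, config@chromLengthBp,
                                groups = groups, seed = seed)
    expected <- if (jShare[1] > jShare[2]) "A"
                else if (jShare[1] < jShare[2]) "B" else NA_character_
    list(config = config, sim = sim, cohort = cohort, calls = calls,
         groups = groups, expected = expected)
}
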