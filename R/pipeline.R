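#' Resolve a run configuration
#'
#' Fills defaults for every stage parameter of the reconstruction
#' pipeline.  The resolved configuration is written beside every stage's
#' outputs so runs are auditable.
#'
#' @param config named list (or YAML file path) overriding defaults.
#' @return named list with all parameters resolved.
#' @export
resolveRunConfig <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    defaults <- list(
        target = "NAT",
        minPosterior = 0.8,
        coverageThreshold = 0.95,
        nIter = 100L,
        windowCm = 0.2,
        windowSites = 50L,
        blockSizeCm = 0.5,
        significance = 0.005,
        masterSeed = 1L,
        spans = NULL)
    cfg <- utils::modifyList(defaults, config)
    stopifnot(cfg$minPosterior >= 0, cfg$minPosterior <= 1,
              cfg$coverageThreshold >= 0, cfg$coverageThreshold <= 1,
              cfg$nIter >= 1, cfg$windowCm > 0, cfg$windowSites >= 10,
              cfg$blockSizeCm > 0, cfg$significance > 0,
              cfg$significance < 1)
    cfg
}

writeResolvedConfig <- function(cfg, outDir, stage) {
    yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                     file.path(outDir, sprintf("config_%s.yaml", stage)))
}

logStage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Pipeline stage: simulate an admixed cohort
#'
#' Writes source and admixed phased VCFs, the genetic map, population
#' labels, ground-truth tracts and window-level local-ancestry calls into
#' \code{outDir}, together with the resolved configuration.
#'
#' @param simConfig a \linkS4class{SimConfig}.
#' @param outDir output directory (created if missing).
#' @param runConfig run configuration (see [resolveRunConfig()]).
#' @param groups optional source -> called-ancestry map passed to
#'   [truthToWindowCalls()].
#' @return invisibly, the list of written paths.
#' @export
pipelineSimulate <- function(simConfig, outDir, runConfig = list(),
                             groups = NULL) {
    cfg <- resolveRunConfig(runConfig)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateSourcePanels(simConfig)
    cohort <- simulateAdmixedCohort(sim, simConfig)
    paths <- list()
    for (lab in names(sim$panels)) {
        p <- file.path(outDir, sprintf("source_%s.vcf", lab))
        writePhasedVcf(sim$panels[[lab]], p)
        paths[[paste0("source_", lab)]] <- p
    }
    paths$admixed <- file.path(outDir, "admixed.vcf")
    writePhasedVcf(cohort$panel, paths$admixed)
    paths$map <- file.path(outDir, "genetic_map.tsv")
    writeGeneticMap(sim$map, paths$map)
    paths$truth <- file.path(outDir, "truth_segments.tsv")
    utils::write.table(cohort$truth, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    calls <- truthToWindowCalls(cohort$truth, sim$map,
                                simConfig@chromLengthBp,
                                windowCm = cfg$windowCm, groups = groups,
                                seed = simConfig@masterSeed)
    paths$calls <- file.path(outDir, "window_calls.tsv")
    writeWindowCalls(calls, paths$calls)
    pops <- data.frame(sample_id = sampleIds(cohort$panel),
                       population = unname(populations(cohort$panel)))
    paths$populations <- file.path(outDir, "populations.tsv")
    utils::write.table(pops, paths$populations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeResolvedConfig(cfg, outDir, "simulate")
    logStage("simulate", "seed %d: %d admixed haplotypes, %d truth rows, %d window calls",
             as.integer(simConfig@masterSeed), ncol(cohort$panel),
             nrow(cohort$truth), length(calls))
    invisible(paths)
}

#' Pipeline stage: extract target-ancestry fragments
#'
#' Runs the posterior filter and window merge ([filterAndMerge()]) on a
#' window-calls TSV and writes the fragments TSV.
#'
#' @param callsPath window-calls TSV.
#' @param outPath fragments TSV to write.
#' @param runConfig run configuration (uses \code{target},
#'   \code{minPosterior}).
#' @return invisibly, the fragments \code{GRanges}.
#' @export
pipelineFragments <- function(callsPath, outPath, runConfig = list()) {
    cfg <- resolveRunConfig(runConfig)
    calls <- readWindowCalls(callsPath)
    frags <- filterAndMerge(calls, cfg$target, cfg$minPosterior)
    writeFragments(frags, outPath)
    writeResolvedConfig(cfg, dirname(outPath), "fragments")
    logStage("fragments", "%d window calls -> %d fragments (target %s, posterior > %.2f)",
             length(calls), length(frags), cfg$target, cfg$minPosterior)
    invisible(frags)
}

#' Default chromosome spans from a panel
#'
#' The coverage denominator used by the jigsaw: per chromosome, the span
#' from the first to the last panel site (the observable span of
#' array-like data), unless overridden in the run configuration.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return named list chrom -> integer (first_bp, last_bp).
#' @export
panelSpans <- function(panel) {
    rr <- rowRanges(panel)
    chroms <- as.character(seqnames(rr))
    pos <- GenomicRanges::start(rr)
    lapply(split(pos, chroms), function(p) c(min(p), max(p)))
}

#' Pipeline stage: jigsaw reconstruction
#'
#' Per autosome: 100 (by default) seeded rearrangement iterations with
#' best-iteration selection; then chromosome pairing into diploid
#' individuals, genotype materialization, and output of the reconstructed
#' phased VCF (half-call dialect), per-haplotype gap BED (0-based
#' half-open), provenance TSV and iteration report TSV.
#'
#' @param fragmentsPath fragments TSV.
#' @param vcfPath source (admixed) phased VCF.
#' @param outDir output directory.
#' @param runConfig run configuration (uses \code{coverageThreshold},
#'   \code{nIter}, \code{masterSeed}, \code{spans}).
#' @return invisibly, a list with the \linkS4class{ReconstructedCohort},
#'   the reconstructed panel and the written paths.  When no
#'   reconstruction is possible the cohort's status says so and no VCF is
#'   written.
#' @export
pipelineReconstruct <- function(fragmentsPath, vcfPath, outDir,
                                runConfig = list()) {
    cfg <- resolveRunConfig(runConfig)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    frags <- readFragments(fragmentsPath)
    panel <- readPhasedVcf(vcfPath)
    spans <- panelSpans(panel)
    if (!is.null(cfg$spans))
        for (ch in names(cfg$spans)) spans[[ch]] <- as.integer(cfg$spans[[ch]])
    chroms <- unique(as.character(seqnames(frags)))
    perAuto <- list()
    report <- list()
    for (ai in seq_along(chroms)) {
        ch <- chroms[ai]
        sub <- frags[as.character(seqnames(frags)) == ch]
        res <- bestIteration(sub, spans[[ch]],
                             threshold = cfg$coverageThreshold,
                             nIter = cfg$nIter,
                             masterSeed = mixSeed(cfg$masterSeed, 3L, ai))
        perAuto[[ch]] <- res
        report[[ch]] <- data.frame(
            autosome = ch,
            iteration = seq_along(attr(res, "iterationCounts")) - 1L,
            n_above_threshold = attr(res, "iterationCounts"))
        logStage("reconstruct", "autosome %s: best iteration %d with %d retained chromosomes",
                 ch, res@iteration, res@nAboveThreshold)
    }
    paths <- list(report = file.path(outDir, "iteration_report.tsv"))
    utils::write.table(do.call(rbind, report), paths$report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cohort <- assemblePopulation(perAuto, seed = mixSeed(cfg$masterSeed, 4L))
    writeResolvedConfig(cfg, outDir, "reconstruct")
    if (cohort@status != "ok") {
        logStage("reconstruct", "status: %s", cohort@status)
        return(invisible(list(cohort = cohort, panel = NULL,
                              paths = paths)))
    }
    mat <- materializeCohort(cohort, panel)
    paths$vcf <- file.path(outDir, "reconstructed.vcf")
    writePhasedVcf(mat$panel, paths$vcf)
    paths$gaps <- file.path(outDir, "gaps.bed")
    writeGapBed(mat$gaps, paths$gaps)
    paths$provenance <- file.path(outDir, "provenance.tsv")
    utils::write.table(provenanceTable(cohort), paths$provenance,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logStage("reconstruct", "%d reconstructed individuals written",
             length(cohort@individuals))
    invisible(list(cohort = cohort, panel = mat$panel, paths = paths))
}

#' Write per-haplotype gap masks as BED
#'
#' Standard BED (0-based, half-open); the name column is
#' \code{individual|side}.
#'
#' @param gaps gap \code{data.frame} from [materializeCohort()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGapBed <- function(gaps, path) {
    bed <- data.frame(chrom = gaps$chrom,
                      start = gaps$start_bp - 1L,
                      end = gaps$end_bp,
                      name = paste0(gaps$individual, "|", gaps$side))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Fragment provenance of a reconstructed cohort
#'
#' @param cohort a \linkS4class{ReconstructedCohort}.
#' @return \code{data.frame}: \code{individual}, \code{autosome},
#'   \code{side}, \code{fragment_id}, \code{source_sample},
#'   \code{source_side}, \code{start_bp}, \code{end_bp}.
#' @export
provenanceTable <- function(cohort) {
    rows <- list()
    for (ind in cohort@individuals)
        for (auto in names(ind@chromosomes))
            for (sidek in 1:2) {
                p <- ind@chromosomes[[auto]][[sidek]]@placements
                if (!length(p)) next
                rows[[length(rows) + 1L]] <- data.frame(
                    individual = ind@id, autosome = auto,
                    side = sidek - 1L, fragment_id = p$fragment_id,
                    source_sample = p$source_sample,
                    source_side = p$source_side,
                    start_bp = start(p), end_bp = end(p))
            }
    if (!length(rows))
        return(data.frame(individual = character(), autosome = character(),
                          side = integer(), fragment_id = character(),
                          source_sample = character(),
                          source_side = integer(), start_bp = integer(),
                          end_bp = integer()))
    do.call(rbind, rows)
}

#' Pipeline stage: reconstruction validation
#'
#' Computes the residual-ancestry f4 check, the alternate-allele frequency
#' correlation between the reconstructed population and the target source
#' panel (at sites covered in the reconstruction), and the pairwise
#' shared-source diagnostic.
#'
#' @param reconstructed reconstructed \linkS4class{HaplotypePanel}.
#' @param cohort the \linkS4class{ReconstructedCohort}.
#' @param targetPanel target-ancestry source panel.
#' @param distractors list of two distractor panels.
#' @param runConfig run configuration (uses \code{blockSizeCm}).
#' @return list: \code{f4} (\linkS4class{FStatResult}),
#'   \code{freqCor}, \code{freqRmse}, \code{nCoveredSites},
#'   \code{sourceOverlap} matrix.
#' @export
pipelineValidate <- function(reconstructed, cohort, targetPanel,
                             distractors, runConfig = list()) {
    cfg <- resolveRunConfig(runConfig)
    fr <- residualAncestryCheck(reconstructed, targetPanel,
                                distractors[[1]], distractors[[2]],
                                blockSizeCm = cfg$blockSizeCm)
    a <- assay(reconstructed, "alleles")
    covered <- rowSums(!is.na(a)) > 0
    fRec <- altFreq(reconstructed)[covered]
    fSrc <- altFreq(targetPanel)[covered]
    ov <- sourceOverlap(cohort@individuals)
    logStage("validate", "f4 Z = %.2f; freq r = %.3f over %d covered sites",
             fr@z, stats::cor(fRec, fSrc), sum(covered))
    list(f4 = fr, freqCor = stats::cor(fRec, fSrc),
         freqRmse = sqrt(mean((fRec - fSrc)^2)),
         nCoveredSites = sum(covered), sourceOverlap = ov)
}

#' Pipeline stage: summary statistics
#'
#' Per-population per-site diversity, the outgroup f3 and residual f4,
#' donor-painting totals and the Wilcoxon/Bonferroni differential-ancestry
#' table, written as TSVs into \code{outDir}.
#'
#' @param reconstructed reconstructed \linkS4class{HaplotypePanel} with a
#'   \code{population} column distinguishing recipient groups.
#' @param donors named list of donor \linkS4class{HaplotypePanel}s.
#' @param outDir output directory.
#' @param runConfig run configuration (uses \code{windowSites},
#'   \code{significance}).
#' @return invisibly, list with \code{pi}, \code{totals}, \code{tests}.
#' @export
pipelineStats <- function(reconstructed, donors, outDir,
                          runConfig = list()) {
    cfg <- resolveRunConfig(runConfig)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pi <- sitePi(reconstructed)
    utils::write.table(pi[!is.na(pi$PI), ],
                       file.path(outDir, "sites.pi.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    totals <- windowPainting(reconstructed, donors,
                             windowSites = cfg$windowSites)
    utils::write.table(data.frame(individual = rownames(totals), totals,
                                  check.names = FALSE),
                       file.path(outDir, "donor_totals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    groups <- populations(reconstructed)
    tests <- differentialAncestryTest(totals, groups,
                                      alpha = cfg$significance)
    utils::write.table(tests, file.path(outDir, "differential_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeResolvedConfig(cfg, outDir, "stats")
    logStage("stats", "%d pi sites, %d x %d donor totals, %d comparisons (%d significant)",
             sum(!is.na(pi$PI)), nrow(totals), ncol(totals), nrow(tests),
             sum(tests$significant))
    invisible(list(pi = pi, totals = totals, tests = tests))
}
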