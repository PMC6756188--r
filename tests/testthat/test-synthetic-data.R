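test_that("source panels follow the Balding-Nichols differentiation model", {
    ## FST -> 0 limit: source frequencies collapse onto the base frequencies
    cfg0 <- SimConfig(nSites = 1000L,
                      sources = data.frame(label = c("A", "B"),
                                           fst = c(0.001, 0.001),
                                           nHaplotypes = c(20L, 20L)),
                      alpha = c(A = 0.5, B = 0.5),
                      nAdmixed = c(d = 2L), masterSeed = 21)
    s0 <- simulateSourcePanels(cfg0)
    expect_lt(mean((s0$sourceFreq[, "A"] - s0$baseFreq)^2), 1e-3)
    ## panel size respected
    expect_equal(ncol(s0$panels$A), 20L)
    expect_equal(nrow(s0$panels$A), 1000L)

    ## FST = 0.1: Hudson estimator between two simulated panels near 0.1
    for (sd in 1:3) {
        cfg <- SimConfig(nSites = 2000L,
                         sources = data.frame(label = c("A", "B"),
                                              fst = c(0.1, 0.1),
                                              nHaplotypes = c(40L, 40L)),
                         alpha = c(A = 0.5, B = 0.5),
                         nAdmixed = c(d = 2L), masterSeed = 100 + sd)
        s <- simulateSourcePanels(cfg)
        p1 <- altFreq(s$panels$A); p2 <- altFreq(s$panels$B)
        ## with both panels at F from the shared base, E[(p1-p2)^2] =
        ## 2 F pbar (1-pbar) and the Hudson denominator averages to
        ## 2 pbar (1-pbar), so the ratio-of-means estimator targets F
        fhat <- hudsonFst(p1, p2, 40, 40)
        expect_lt(abs(fhat - 0.1), 0.03)
    }
})

test_that("admixed haplotypes have calibrated switch counts and ancestry dose", {
    ## alpha = (0.5, 0.5), G = 20, L = 1 Morgan -> E[visible switches] = 10
    cfg <- SimConfig(nSites = 200L,
                     sources = data.frame(label = c("A", "B"),
                                          fst = c(0.1, 0.1),
                                          nHaplotypes = c(20L, 20L)),
                     alpha = c(A = 0.5, B = 0.5),
                     nAdmixed = c(d = 250L), masterSeed = 5)
    sim <- simulateSourcePanels(cfg)
    co <- simulateAdmixedCohort(sim, cfg)
    ts <- truthSummary(co$truth)
    expect_equal(nrow(ts), 500L)
    expectSwitch <- 20 * 1 * (1 - 0.5^2 - 0.5^2)
    se <- sd(ts$n_switches) / sqrt(nrow(ts))
    expect_lt(abs(mean(ts$n_switches) - expectSwitch), 3 * se)
    ## ancestry dose unbiased
    seA <- sd(ts$A) / sqrt(nrow(ts))
    expect_lt(abs(mean(ts$A) - 0.5), 3 * seA)
})

test_that("the low-ancestry scenario delivers ~7% target genome fraction", {
    cfg <- SimConfig(nSites = 200L, nAdmixed = c(d = 250L), masterSeed = 8)
    sim <- simulateSourcePanels(cfg)
    co <- simulateAdmixedCohort(sim, cfg)
    ts <- truthSummary(co$truth)
    se <- sd(ts$NAT) / sqrt(nrow(ts))
    expect_lt(abs(mean(ts$NAT) - 0.07), 3 * se)
})

test_that("degenerate admixture copies everything from the single source", {
    cfg <- SimConfig(nSites = 500L,
                     sources = data.frame(label = c("A", "B"),
                                          fst = c(0.1, 0.1),
                                          nHaplotypes = c(20L, 20L)),
                     alpha = c(A = 1, B = 0),
                     nAdmixed = c(d = 30L), masterSeed = 3)
    sim <- simulateSourcePanels(cfg)
    co <- simulateAdmixedCohort(sim, cfg)
    expect_true(all(co$truth$source == "A"))
    ## admixed frequencies track the source-A panel within binomial error
    fA <- altFreq(sim$panels$A); fC <- altFreq(co$panel)
    expect_lt(mean(abs(fC - fA)), 4 * mean(sqrt(fA * (1 - fA) / 60)))
})

test_that("truth segments partition the chromosome and copy donor alleles", {
    cfg <- SimConfig(nSites = 300L, nAdmixed = c(d = 10L), masterSeed = 13)
    sim <- simulateSourcePanels(cfg)
    co <- simulateAdmixedCohort(sim, cfg)
    tr <- co$truth
    for (k in split(seq_len(nrow(tr)), paste(tr$sample_id, tr$side))) {
        seg <- tr[k, ][order(tr$start_bp[k]), ]
        expect_equal(seg$start_bp[1], 1)
        expect_equal(seg$end_bp[nrow(seg)], cfg@chromLengthBp)
        if (nrow(seg) > 1)
            expect_true(all(seg$start_bp[-1] == seg$end_bp[-nrow(seg)] + 1))
        expect_true(all(seg$end_bp >= seg$start_bp))
    }
    ## alleles equal the recorded donor haplotype's alleles on every tract
    pos <- start(rowRanges(co$panel))
    colKeyAdm <- paste(haplotypeSample(co$panel), haplotypeSide(co$panel))
    for (r in sample.int(nrow(tr), 50)) {
        i <- which(pos >= tr$start_bp[r] & pos <= tr$end_bp[r])
        if (!length(i)) next
        adm <- alleles(co$panel)[i, match(paste(tr$sample_id[r], tr$side[r]),
                                          colKeyAdm)]
        don <- alleles(sim$panels[[tr$source[r]]])[i, tr$donor_hap[r]]
        expect_identical(unname(adm), unname(don))
    }
})

test_that("window calls reflect majority-bp ancestry per window", {
    map <- uniformGeneticMap("1", 1000L, 1)
    ## one haplotype, tract boundary inside window 2 with a 60/40 split
    truth <- data.frame(sample_id = "h1", side = 0L, deme = "d",
                        chrom = "1",
                        start_bp = c(1, 801), end_bp = c(800, 1000),
                        source = c("J", "T"),
                        donor_hap = "x")
    calls <- truthToWindowCalls(truth, map, 1000L, windowCm = 0.5)
    expect_length(calls, 2L)
    ## window 2 spans (501, 1000): 300 bp J vs 200 bp T -> J
    expect_equal(S4Vectors::mcols(calls)$J, c(1, 1))

    ## single-ancestry haplotype: every window posterior 1 on that ancestry
    t2 <- truth; t2$source <- "J"
    c2 <- truthToWindowCalls(t2, map, 1000L, windowCm = 0.5,
                             labels = c("J", "T"))
    expect_true(all(S4Vectors::mcols(c2)$J == 1))

    ## eps soft noise keeps the true label dominant
    c3 <- truthToWindowCalls(t2, map, 1000L, windowCm = 0.5, eps = 0.1,
                             labels = c("J", "T"))
    expect_true(all(abs(S4Vectors::mcols(c3)$J - 0.9) < 1e-12))
})

test_that("clean window calls round-trip to the true tract set up to quantization", {
    cfg <- SimConfig(nSites = 200L, nAdmixed = c(d = 20L),
                     alpha = c(NAT = 0.3, EUR = 0.4, AFR = 0.3),
                     masterSeed = 31)
    sim <- simulateSourcePanels(cfg)
    co <- simulateAdmixedCohort(sim, cfg)
    calls <- truthToWindowCalls(co$truth, sim$map, cfg@chromLengthBp)
    fr <- filterAndMerge(calls, "NAT")
    windowBp <- 0.2 / cfg@totalCm * cfg@chromLengthBp
    tr <- co$truth[co$truth$source == "NAT", ]
    trueBp <- sum(tr$end_bp - tr$start_bp + 1)
    fragBp <- sum(width(fr))
    ## each tract boundary can move by at most one window
    nBound <- 2 * nrow(tr)
    expect_lt(abs(fragBp - trueBp), nBound * windowBp)
    ## every merged fragment overlaps true target sequence over most of its
    ## length: per-haplotype agreement of painted bp
    ovl <- 0
    for (r in seq_len(nrow(tr))) {
        same <- fr[fr$source_sample == tr$sample_id[r] &
                   fr$source_side == tr$side[r]]
        if (!length(same)) next
        ovl <- ovl + sum(pmax(0, pmin(end(same), tr$end_bp[r]) -
                                  pmax(start(same), tr$start_bp[r]) + 1))
    }
    expect_gt(ovl / fragBp, 0.95)
})

test_that("the differential scenario realizes its designed source shares", {
    for (sd in 1:3) {
        sc <- scenarioDifferential(nAdmixed = 40L, nSites = 300L, seed = sd)
        ts <- truthSummary(sc$cohort$truth)
        tgt <- ts$J + ts$T
        shareJ_A <- sum(ts$J[ts$deme == "A"]) / sum(tgt[ts$deme == "A"])
        shareJ_B <- sum(ts$J[ts$deme == "B"]) / sum(tgt[ts$deme == "B"])
        expect_lt(abs(shareJ_A - 0.8), 0.08)
        expect_lt(abs(shareJ_B - 0.2), 0.08)
        expect_equal(sc$expected, "A")
    }
    ## symmetric null: both demes draw target ancestry 50/50
    scn <- scenarioDifferential(nAdmixed = 40L, nSites = 300L,
                                jShare = c(0.5, 0.5), seed = 4)
    tsn <- truthSummary(scn$cohort$truth)
    tgtn <- tsn$J + tsn$T
    expect_lt(abs(sum(tsn$J[tsn$deme == "A"]) / sum(tgtn[tsn$deme == "A"]) -
                  sum(tsn$J[tsn$deme == "B"]) / sum(tgtn[tsn$deme == "B"])),
              0.08)
    expect_true(is.na(scn$expected))
})

test_that("invalid simulation configurations are rejected", {
    expect_error(SimConfig(alpha = c(NAT = 0.5, EUR = 0.6, AFR = 0.1)),
                 "sum to 1")
    expect_error(SimConfig(sources = data.frame(
        label = c("NAT", "EUR", "AFR"), fst = c(0, 0.1, 0.1),
        nHaplotypes = c(20L, 20L, 20L))), "FST")
    expect_error(SimConfig(G = 0), "G must be")
    cfg <- SimConfig(nSites = 50L, nAdmixed = c(d = 2L))
    sim <- simulateSourcePanels(cfg)
    bad <- cfg
    bad@alpha <- matrix(c(0.5, 0.5), 1, 2,
                        dimnames = list("d", c("NAT", "XX")))
    expect_error(simulateAdmixedCohort(sim, bad), "no simulated panel")
})
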