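---
title: "Reconstructing ancestral populations from admixed genomes: methods and design"
author: "AncestryJigsaw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral populations from admixed genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many ancestral populations survive today only inside admixed genomes: a
few percent of target ancestry scattered as short haplotype fragments
through a cohort whose genomes are otherwise of other ancestries. Local
ancestry inference can label those fragments, but most population-genetic
machinery (haplotype painting, f-statistics, diversity estimation) wants
individuals of *full* target ancestry. AncestryJigsaw closes that gap: it
rearranges the labelled fragments, without breaking or overlapping them,
into virtual chromosomes of complete target ancestry, assembles those into
reconstructed diploid individuals, and supplies the statistics used to
check that the reconstruction is faithful.

## The reconstruction procedure

**Inputs.** Phased biallelic genotypes (VCF with phased GT), per-window
local-ancestry posterior calls in a documented TSV dialect (one row per
haplotype and window, one posterior column per ancestry; any RFMix-class
tool can be converted to it), a genetic map, and population labels. All
coordinates are 1-based inclusive.

**Posterior filter and merge** (`filterAndMerge`). A window is kept iff
its target-ancestry posterior is *strictly* greater than `minPosterior`
(default 0.8). Within a haplotype, maximal runs of kept windows that are
consecutive in the window sequence become one fragment spanning the first
window's start to the last window's end. Consecutive means adjacent in
the window grid, not adjacent in base pairs: two kept windows separated
by a discarded window are never merged. Each fragment records its source
haplotype — provenance that survives all later stages.

**Greedy tiling** (`sortPool`, `tileOnce`, `rearrangeIteration`). Per
autosome, the fragment pool is sorted by start base pair; fragments
sharing a start are permuted uniformly at random (the only randomness in
an iteration). A tiling pass scans the pool left to right and places a
fragment whenever its start exceeds the end of the last placed fragment;
the first fragment is always placed. Skipped intervals are gaps, treated
as missing sequence. Passes repeat on the remaining pool — each new pass
restarting from the lowest available start — until the pool is empty, so
each fragment is used exactly once per iteration. A rearranged chromosome
is retained when its placements cover at least `coverageThreshold`
(default 0.95) of the chromosome span.

**Iteration selection** (`bestIteration`). `nIter` (default 100)
iterations run with per-iteration seeds derived from the master seed; the
iteration retaining the most chromosomes wins, ties breaking to the
lowest index so results are bit-reproducible.

**Diploid assembly** (`assemblePopulation`). The autosome with the fewest
retained chromosomes sets the number of reconstructed chromosomes; the
number of individuals is half that, rounded down. Retained chromosomes
are shuffled (seeded) and paired consecutively; excess chromosomes are
discarded. If any autosome retains none, the result is the explicit
status "no reconstruction possible" rather than an empty object.

**Materialization** (`materializeCohort`). Every site inside a placement
carries the source haplotype's allele — fragment-internal phase is
preserved exactly, since fragments are never broken — and sites inside
gaps are missing. The output VCF uses a half-call dialect (`0|.`) and is
accompanied by a per-haplotype gap BED so downstream tools that reject
half-calls can mask instead. We deliberately do not re-phase the output:
phase is exact within fragments, and between-fragment phase is
meaningless by construction.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `minPosterior` | 0.8 | posterior prob. | strict filter on target windows |
| `coverageThreshold` | 0.95 | fraction of span | retention of rearranged chromosomes |
| `nIter` | 100 | iterations | tie-order search breadth |
| `windowCm` | 0.2 | cM | window grid of the simulated calls |
| `G` | 20 | generations | admixture-pulse age (switch rate per Morgan) |
| `windowSites` | 50 | sites | painting window (minimum 10) |
| `blockSizeCm` | 0.5 | cM | f-statistic jackknife block |
| `significance` | 0.005 | corrected p | differential-ancestry flag |

The defaults for the filter, threshold, iteration count, window size and
pulse age are the standard operating point of this class of analysis;
`blockSizeCm = 0.5` is sized to the simulator's 1-Morgan chromosome (200
blocks) — on genome-scale data one would use centimorgan-scale blocks in
the single digits.

## Design decisions where the procedure is underdetermined

*Coverage denominator.* "The chromosome" is ambiguous on array data. We
default the span to [first site, last site] of the panel per chromosome
(`panelSpans`), overridable via configuration (the simulator's fixtures
pass the full simulated chromosome). Coverage is computed by exact
integer base-pair arithmetic on placements clipped to the span, so gaps
and placements partition the span.

*Threshold strictness.* Kept windows require posterior strictly above
0.8; a window at exactly 0.8 is discarded. Retention uses coverage
greater than or equal to the threshold.

*Failed chromosomes.* Fragments of below-threshold chromosomes stay
consumed within their iteration; optimization happens *across* seeded
iterations, not by re-tiling within one. This keeps iterations
independent and cheap, and matches the selection-over-iterations design.

*Pairing and odd counts.* Which chromosomes are surplus when the retained
count is odd is decided by the seeded shuffle, not by coverage rank —
retained chromosomes are exchangeable by construction.

*Seed schedule.* All randomness flows root → stage → autosome → iteration
through one documented mixing function (`mixSeed`, a
multiplicative-congruential scramble modulo 2^31 − 1, exact in doubles).
No global RNG state leaks: seeded sections restore the caller's RNG.

## The statistics

*Per-site diversity.* π = 2c(n−c)/(n(n−1)) with n the non-missing
alleles and c the alternate count — the `--site-pi` closed form — with
half-calls excluded from n and sites with n < 2 skipped.

*f-statistics.* f4(A,B;C,D) is the site-mean of (p_A−p_B)(p_C−p_D), f3
the analogous shared-drift form. Sites where any population is entirely
missing are skipped. Standard errors use a leave-one-block-out jackknife
over genetic-map blocks, weighted for unequal block sizes; Z =
estimate/SE. The residual-ancestry check is f4(reconstructed, target
source; distractor1, distractor2), with |Z| < 4 read as "no residual
ancestry". Note that contamination split *evenly* between the two
distractors cancels in this f4 by symmetry; the positive control in the
tests therefore contaminates from a single distractor, which is also the
realistic failure mode (miscalling one specific ancestry as target).

*Donor painting.* A deliberately simple surrogate for model-based
chromosome painting: recipient haplotypes are cut into windows of
`windowSites` sites; each window goes to the donor population containing
a minimum-Hamming haplotype (missing recipient sites excluded; ties split
equally), and window lengths are measured in cM from midpoint boundaries
so each recipient's row sums to its painted genetic length. This is not a
Li–Stephens copying model: absolute chunk lengths are not comparable to
model-based painters, and downstream comparisons use only direction and
rank, which are robust to the simplification.

*Differential ancestry.* For each donor and each unordered pair of
recipient groups, a two-sided Wilcoxon rank-sum test (exact for small
samples without ties, normal approximation with continuity correction
otherwise — the behaviour of `stats::wilcox.test`) compares donor totals;
Bonferroni correction runs over all donor × pair tests performed in the
call — the family is the run, which is the configurable, conservative
reading — and comparisons are flagged at corrected p < 0.005. Rank-sum
rather than signed-rank because the recipient groups are distinct
populations, not paired observations.

## What the simulator emulates — and what it does not

`simulateSourcePanels` draws per-site base frequencies uniform on
(0.05, 0.95) and source-panel frequencies from the Balding–Nichols
distribution Beta(p(1−F)/F, (1−p)(1−F)/F), giving panels whose pairwise
Hudson FST matches the nominal F. `simulateAdmixedCohort` lays down
switch points as a Poisson process of rate G per Morgan, draws the
ancestry of each inter-switch segment independently from the deme's
admixture vector α (so a switch is *visible* with probability 1 − Σα²,
and the expected visible-switch count is G·L·(1 − Σα²)), and copies each
segment from a uniformly chosen donor haplotype of that source's panel.
Ground truth (tract spans, source, donor haplotype) is recorded per
haplotype, and `truthToWindowCalls` converts it to RFMix-style window
calls at 0.2 cM, with majority-base-pair assignment inside boundary
windows, an optional symmetric softening ε of the posteriors, and an
optional contamination knob that relabels non-target windows as target.

The default single-deme configuration is the study condition this method
is built for: three continental sources at FST 0.1, a single pulse G = 20
generations ago, and a low (7% on average) target-ancestry proportion.
The differential scenario (`scenarioDifferential`) builds two target
sources about FST 0.05 apart plus two distractors, with demes drawing
their target ancestry 80/20 versus 20/80 from the two target sources —
an asymmetry of origins of the kind the donor-sharing comparison is meant
to detect — and a symmetric 50/50 variant as its null.

Deliberately out of scope: demographic realism (growth, bottlenecks,
continuous migration), linkage disequilibrium within source panels
(sites are independent given frequencies), genotyping error beyond the
ε/contamination knobs, and real local-ancestry inference error
structure. Passing tests on these simulations therefore demonstrate the
*procedure* — filtering, tiling, assembly, statistics — not the accuracy
of any upstream local-ancestry tool on real data.

## Problem sizes and numerical notes

The packaged analyses run at desk scale, chosen once: one chromosome of
1 Morgan with 2,000 sites; 200 admixed diploids at α_target = 0.3 for the
recovery and residual-ancestry runs (100 jigsaw iterations); 200 diploids
per deme at α_target = 0.4, 10 iterations, and 50 reconstructed
individuals per deme for the differential design; 500 haplotypes for the
simulator calibration checks. Posterior vectors must sum to 1 within
1e-6. Window majority ties inside `truthToWindowCalls` break to the first
label alphabetically (they have probability ~0 under continuous maps).
Degenerate inputs are first-class: empty pools error in `tileOnce`,
empty fragment lists produce empty (not missing) outputs, fragments
spanning no panel sites warn and copy nothing, and a cohort in which any
autosome retains no chromosome reports "no reconstruction possible".

## Known limitations

- Greedy tiling is not maximum-coverage interval scheduling; the
  iteration search only randomizes tie order, so yield is a lower bound
  on what an optimal tiler could retain.
- Reconstructed individuals are not biological entities: fragments from
  one real individual can end up in several reconstructed individuals.
  `sourceOverlap` quantifies exactly this sharing (fraction of genome
  where two reconstructed individuals carry fragments from the same
  source individual) so kinship-sensitive downstream analyses can be
  screened.
- Between-fragment phase in the output is arbitrary; only
  fragment-internal haplotype structure is meaningful.
- The painting surrogate is assignment-based, not probabilistic; use its
  totals for comparisons, not as absolute coancestry estimates.
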