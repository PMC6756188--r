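Package: AncestryJigsaw
Title: Reconstruction of Ancestral Populations from Local-Ancestry
    Fragments of Admixed Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs virtual individuals of full target ancestry from
    the ancestry-specific haplotype fragments of admixed genomes. Windows of
    local-ancestry calls are filtered by posterior probability, merged into
    contiguous fragments, and greedily tiled into non-overlapping
    "rearranged" chromosomes; retained chromosomes (by base-pair coverage)
    are paired into reconstructed diploid individuals. Includes a
    Balding-Nichols / single-pulse admixture simulator with ground-truth
    ancestry tracts, and validation statistics: per-site nucleotide
    diversity, f3/f4 with weighted block jackknife, a minimum-mismatch
    haplotype-painting surrogate, and Wilcoxon/Bonferroni
    differential-ancestry tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, PopulationGenetics, Software
RoxygenNote: 7.3.3
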