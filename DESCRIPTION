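Package: poolSweeps
Title: Two-Slope Pooled-Sequencing Diversity, Sweep and Repeatome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic analysis of pooled isofemale-line sequencing from
    paired habitats ("slopes"): pooled diversity statistics (heterozygosity,
    Watterson's theta, Tajima's D, per-SNP FST) in tiling windows and per gene;
    a three-state hidden Markov model that segments each line's allele-frequency
    spectrum into Neutral, Intermediate and Selection states to call selective
    sweep regions; per-gene differential sweep scores contrasting the two slopes;
    transspecies shared-polymorphism statistics including major-allele
    co-occurrence and slope-divergent nonsynonymous filtering; and transposable
    element insertion sharing, abundance and density analysis. Includes a
    calibrated two-slope synthetic cohort generator with known ground truth so
    every stage is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
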