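Package: gscar
Title: Genomic Scar Analysis for Homologous Recombination Deficiency Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls allele-specific copy number from per-bin B-allele-frequency
    (BAF) and log R ratio (LRR) tracks produced by targeted SNP-panel
    sequencing, and scores homologous recombination deficiency (HRD) from the
    resulting profile. The pipeline covers noise filtering, tree-recursion
    changepoint segmentation of the BAF and LRR tracks, kernel-density-based
    segment merging, density clustering of segments into genotypes, joint
    estimation of tumor purity and the ploidy correction factor, integer
    allele-specific copy-number assignment, and the three genomic scar
    counters (loss of heterozygosity, telomeric allelic imbalance,
    large-scale state transitions) combined into a ploidy-corrected HRD
    score. A track-level simulator with known ground truth supports
    validation, including purity dilution series. A SNP-level majority-vote
    caller reports locus-specific loss of heterozygosity over a gene.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
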