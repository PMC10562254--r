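Package: hybridsel
Title: Quantitative Genomics of Hybrid Rice Heterosis and Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative-genomic studies of
    hybrid rice breeding. Generates founder, F1 and F2 cohorts with known ground
    truth (differentiated subspecies panels, Haldane meiosis, additive plus
    dominance trait architectures); calls indica-japonica differentiated SNPs
    from reference panels and scans samples for heterozygous and homozygous
    japonica introgression with a sliding-window rule; estimates per-locus
    degree of dominance (d/a) and breeding-favorable alleles; partitions
    phenotypic variance around association signals with a four-kernel REML
    mixed model; and fits additive(+dominance) GBLUP genomic-selection models
    with cross-validation, pseudo-combination enumeration, a multi-trait
    selection index and sterility-locus screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
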