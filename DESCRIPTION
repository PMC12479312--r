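Package: superhla
Title: HLA Class I Superdonor Discovery, Compatibility Modeling and Guide Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing HLA class I (HLA-A, HLA-B, HLA-C) genotype
    registries in the context of haplobank and regenerative-medicine donor
    selection. Provides allele nomenclature parsing at one- to four-field
    resolution, allele-frequency and homozygosity accounting, multi-allele
    Hardy-Weinberg equilibrium testing, cross-population comparison by
    frequency regression and PCA of one-hot encoded genotypes, a
    donor-to-recipient immune-compatibility model covering natural and
    gene-edited (HLA-C retained) configurations with population-coverage
    simulation, and a CRISPR-Cas9 guide-RNA design cascade (NGG site
    extraction, Rule Set 1 on-target activity scoring, ectodomain filtering
    and HLA-C-sparing selection). A synthetic-data module generates
    registries with controlled homozygote excess and annotated toy genes so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
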