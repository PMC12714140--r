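Package: nbscreen
Title: Variant Prioritization and Validation for Genomic Newborn Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine that decides which small variants and copy-number
    variants in a panel of gene-condition pairs are flagged for clinical
    scientist review in a genomic newborn screening programme. Implements
    variant normalization and MNV decomposition, per-source pathogenicity
    rules over ClinVar-like knowledge bases (including handling of variants
    with conflicting interpretations of pathogenicity), predicted
    loss-of-function rules with MANE-aware transcript selection,
    mode-of-inheritance gating with read-based phasing of potential compound
    heterozygotes, CNV reciprocal-overlap frequency filtering, gene-level
    coverage and CNV-callability QC gating, and a specificity/sensitivity
    evaluation framework with Wilson score intervals and two-proportion
    tests. A synthetic-cohort generator produces fully controlled fixtures
    (VCFs, knowledge bases, frequency references, depth tracks) so every
    component is testable without access to controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
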