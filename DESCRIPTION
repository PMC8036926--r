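Package: lopdkit
Title: Clinical Severity Scoring and Family-Based Modifier-Gene
    Prioritization for Late-Onset Pompe Disease
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying phenotype variability in late-onset Pompe
    disease (LOPD) sibships. Implements a 14-item ordinal clinical Severity
    Index (grading, summation, severity classes and cohort dichotomization),
    small-sample cohort statistics (exact Mann-Whitney U with mid-rank tie
    handling, chi-square, Pearson correlation), a rare-variant modifier-gene
    prioritization cascade (quality control, functional-class, allele
    frequency and CADD deleteriousness filters, between- and within-family
    carrier sharing, dichotomized-phenotype cosegregation, hypergeometric
    gene-set enrichment), and a seeded synthetic cohort/variant generator
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
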