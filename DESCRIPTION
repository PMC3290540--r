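Package: poescan
Title: Parent-of-Origin Effect Scans for Litter Traits in Pedigreed Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-SNP association scans for additive, dominance and
    parent-of-origin (imprinting) effects on repeated litter records in
    pedigreed livestock populations. Provides pedigree validation and
    additive-relationship matrices, Mendelian-consistency screening and
    rule-based parental-origin assignment of marker alleles, litter-record
    filters, restricted maximum likelihood (REML) estimation of additive,
    permanent-environment, maternal and residual variance components,
    generalized least squares marker scans with ordered-genotype contrasts
    and incremental F-tests, Storey-Tibshirani q-values, and a gene-drop
    simulator of half-sib pig populations for validation and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, methods, stats, utils, yaml, vcfR
Suggests: testthat (>= 3.0.0), lme4, optparse, jsonlite, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
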