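Package: fampoly
Title: Family-Based GWAS Pipeline for Nasal Polyposis with Directed eQTL Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain of a
    family-based genome-wide association study of chronic rhinosinusitis
    with nasal polyps (CRSwNP): cohort quality control (missingness,
    heterozygosity, Mendelian errors, LD pruning, PCA ancestry outliers),
    two family-aware association scans (a DFAM-style stratified
    Cochran-Mantel-Haenszel test and an EMMAX-style mixed model over
    additive/dominant/recessive codings), LD-interval gene-set enrichment
    with matched random-region permutations, two-group differential
    expression with Benjamini-Hochberg FDR control, and a directed eQTL
    enrichment test with a matched-gene empirical null. A synthetic-data
    module simulates pedigreed genotypes, eQTL catalogues and expression
    matrices with the statistical structure the analysis assumes, so the
    whole pipeline is testable without access to cohort genotypes or
    external reference resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
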