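Package: smrmwas
Title: Summary-Based Methylome-Wide Association Analysis with SMR and HEIDI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates GWAS and cis-mQTL summary statistics to detect CpG
    methylation sites whose genetically driven variation is associated with a
    disease, using the summary-data-based Mendelian randomization (SMR) ratio
    test with the heterogeneity-in-dependent-instruments (HEIDI) filter that
    separates pleiotropy at a single locus from linkage between distinct causal
    variants. Includes inverse-variance fixed-effects meta-analysis of
    per-cohort GWAS tables with allele harmonization, Wald chi-square scans for
    group-specific (sex- or hypertension-stratified) effects, cross-tissue
    concordance summaries, probe-to-gene annotation with catalog-based locus
    classification, competitive gene-set enrichment with a false-discovery-rate
    level selection rule, and a synthetic-data generator that simulates
    LD-structured reference panels plus matched mQTL and multi-cohort
    case-control GWAS summary statistics under null, pleiotropy, linkage and
    group-heterogeneity scenarios with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
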