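Package: proteosig
Title: Sex-Stratified Differential Proteomics and Phosphoproteomics with
    Signature Reversal, Site-Set Enrichment and Target-Centric Consensus
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for label-free quantitative proteomics
    and phosphoproteomics of factorial mouse designs (genotype x treatment,
    stratified by sex). Provides MaxQuant-dialect ingest with quality-control
    filters, log2/kNN/median-centering and quantile/low-rank preprocessing,
    empirical-Bayes moderated t-statistics for pairwise contrasts, signed
    signature overlap and reversal statistics, sample-wise phosphosite-set
    enrichment scoring, gene-set overrepresentation and ranked enrichment,
    a target-centric consensus co-expression network built by directional
    voting across cohorts, and Fisher-exact signaling maps. A synthetic-data
    generator with planted ground truth makes every stage testable without
    access to deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
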