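Package: sumtwas
Title: Summary-Statistic Inference for Transcriptome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream inference chain for transcriptome-wide association
    studies (TWAS) computed entirely from GWAS summary statistics, expression
    SNP-weight panels and an LD reference: per-feature association statistics,
    correlation-aware transcriptome-wide significance thresholds, joint and
    conditional analysis of multi-feature regions, omnibus pooling of a gene's
    evidence across weight panels, approximate-Bayes-factor colocalization,
    competitive gene-set / gene-property / weight-panel enrichment via a
    linear mixed model on the feature-relatedness matrix, and TWAS-weighted
    stratified LD score regression with liability-scale conversion. A
    synthetic-data generator with known ground truth (LD blocks, sparse cis
    weights, gene-mediated GWAS effects, enriched gene sets) supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
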