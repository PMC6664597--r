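#!/usr/bin/env Rscript
# Competitive enrichment via the linear mixed model on the
# feature-relatedness matrix: candidate gene sets, developmental-stage
# property gradients, and panel-vs-panel weight-set enrichment.

suppressMessages({ library(sumtwas); library(data.table) })

dat <- "results/data"
ld <- read_ld_bundle(file.path(dat, "ld"))
panel <- assign_panel_blocks(read_weight_bundle(file.path(dat, "weights")), ld)
res <- fread("results/twas_results.tsv")
sets <- read_gmt(file.path(dat, "gene_sets.gmt"))
stages <- read_property_scores(file.path(dat, "stage_scores.tsv"))
truth <- fread(file.path(dat, "truth_sets.tsv"))

fc <- feature_correlations(panel, ld)
rel <- build_feature_relatedness(fc)
ord <- match(rel$feature_id, res$FEATURE_ID)
z <- association_z_transform(res$TWAS_P)[ord]
gid <- res$GENE_ID[ord]
labs <- res$PANEL[ord]

message("gene-set enrichment over ", length(sets), " sets")
enr <- enrichment_gene_sets(z, gid, sets, rel)
hits <- enr[fdr_p < 0.05, set_id]
message(sprintf("  FDR < 0.05: %d set(s) [%s]; truly enriched: %s",
                length(hits), paste(hits, collapse = ","),
                paste(truth[enriched == TRUE, set_id], collapse = ",")))
fwrite(enr[order(p_one_sided)], "results/enrichment_sets.tsv", sep = "\t")

message("property-gradient tests across ",
        ncol(stages) - 1, " developmental stages")
sc <- as.matrix(stages[match(gid, gene), -"gene"])
prop <- property_gradient_test(z, sc, rel)
message(sprintf("  %d stage(s) pass Bonferroni (0.05/%d); min p = %.2g",
                sum(prop$bonf_sig), nrow(prop), min(prop$p_two_sided)))
fwrite(prop, "results/enrichment_stages.tsv", sep = "\t")

message("weight-set (panel) enrichment")
pan <- weight_set_enrichment(z, labs, rel)
for (i in seq_len(nrow(pan)))
  message(sprintf("  %s: beta = %+.3f, one-sided p = %.3f",
                  pan$set_id[i], pan$beta[i], pan$p_one_sided[i]))
fwrite(pan, "results/enrichment_panels.tsv", sep = "\t")
message("wrote results/enrichment_{sets,stages,panels}.tsv")
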