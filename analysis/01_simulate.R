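#!/usr/bin/env Rscript
# Generate the synthetic study: an LD reference, two SNP-weight panels over
# shared genes (a brain-like and a blood-like panel), gene sets of which a
# few are truly enriched, developmental-stage property scores, and GWAS
# summary statistics whose signal is partly mediated by predicted
# expression. Everything is written as plain-text bundles under
# results/data/ with the ground truth alongside.

suppressMessages({ library(sumtwas); library(data.table) })

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

message("simulating LD reference: 40 blocks x 100 SNPs, AR(1) rho = 0.8")
ld <- simulate_ld_blocks(40, 100, 0.8, seed = seed)

message("simulating two weight panels over 400 shared genes")
genes <- sprintf("G%05d", 1:400)
panel_a <- simulate_weight_panel(ld, 400, 0.05, 0.2, seed = seed + 1,
                                 panel_id = "BRAIN", gene_ids = genes)
panel_b <- simulate_weight_panel(ld, 400, 0.05, 0.2, seed = seed + 2,
                                 panel_id = "BLOOD", gene_ids = genes)
panel <- structure(list(features = rbind(panel_a$features, panel_b$features),
                        weights = c(panel_a$weights, panel_b$weights)),
                   class = "weight_panel")

message("drawing gene sets (3 of 100 enriched) and stage scores")
gs <- simulate_gene_sets_and_properties(
  panel, n_sets = 100, set_size = 20, enriched_effect = 3e-4,
  gene_effect_sd = sqrt(0.0156 / 800), n_enriched = 3, prop_cor = 0.3,
  seed = seed + 3)

message("simulating GWAS summary statistics (N = 46,350)")
ss <- simulate_gwas_sumstats(ld, panel, gs$alpha,
                             direct_effect_sd = sqrt(0.1044 / 4000),
                             n_gwas = 46350, seed = seed + 4)

write_ld_bundle(ld, file.path(out, "ld"))
write_weight_bundle(panel, file.path(out, "weights"))
write_sumstats(ss, file.path(out, "gwas.sumstats"))
write_gmt(gs$sets, file.path(out, "gene_sets.gmt"))
write_property_scores(gs$properties, file.path(out, "stage_scores.tsv"))
fwrite(gs$truth$features, file.path(out, "truth_features.tsv"), sep = "\t")
fwrite(gs$truth$sets, file.path(out, "truth_sets.tsv"), sep = "\t")

message(sprintf("true mediated h2 = %.4f over %d features; %d enriched sets",
                sum(gs$alpha^2), nrow(panel$features),
                sum(gs$truth$sets$enriched)))
message("wrote ", out)
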