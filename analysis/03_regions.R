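#!/usr/bin/env Rscript
# Joint/conditional analysis of regions with multiple significant features,
# conditioning of the top GWAS SNP on predicted expression, the SNP-wise
# mean gene test, and the omnibus pooling of each gene across panels.

suppressMessages({ library(sumtwas); library(data.table) })

dat <- "results/data"
ld <- read_ld_bundle(file.path(dat, "ld"))
panel <- assign_panel_blocks(read_weight_bundle(file.path(dat, "weights")), ld)
ss <- read_sumstats(file.path(dat, "gwas.sumstats"))
res <- fread("results/twas_results.tsv")
setnames(res, tolower(names(res)))
setnames(res, c("chr"), c("chrom"))
thr <- fread("results/significance_threshold.tsv")$threshold_p
fc <- feature_correlations(panel, ld)

reg <- region_report(res, ss, panel, ld, fc, threshold = thr)
if (nrow(reg) > 0) {
  message(nrow(reg), " region(s) of transcriptome-wide significant features:")
  for (i in seq_len(nrow(reg)))
    message(sprintf("  %s  minP(TWAS)=%.2g  minP(GWAS)=%.2g  %.1f%% of top SNP explained; joint: %s",
                    reg$location[i], reg$minp_twas[i], reg$minp_gwas[i],
                    reg$var_explained_pct[i], reg$jointly_sig[i]))
} else message("no transcriptome-wide significant regions in this study")
fwrite(reg, "results/regions.tsv", sep = "\t")

# omnibus: pool each gene's evidence across the two panels
Cfull <- as.matrix(fc)
omni <- rbindlist(lapply(split(res, res$gene_id), function(g) {
  if (nrow(g) < 2L) return(NULL)
  idx <- match(g$feature_id, colnames(Cfull))
  if (anyNA(idx)) return(NULL)
  o <- omnibus_test(g$twas_z, Cfull[idx, idx])
  data.table(gene_id = g$gene_id[1], n_panels = nrow(g),
             stat = o$stat, df = o$df, p = o$p)
}))
message(sprintf("omnibus test over %d multi-panel genes; min p = %.2g",
                nrow(omni), min(omni$p)))
fwrite(omni[order(p)], "results/omnibus.tsv", sep = "\t")
message("wrote results/regions.tsv, results/omnibus.tsv")
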