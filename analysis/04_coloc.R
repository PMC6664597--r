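#!/usr/bin/env Rscript
# Approximate-Bayes-factor colocalization of the GWAS signal with each
# transcriptome-wide significant feature's expression signal.

suppressMessages({ library(sumtwas); library(data.table) })

dat <- "results/data"
ld <- read_ld_bundle(file.path(dat, "ld"))
panel <- assign_panel_blocks(read_weight_bundle(file.path(dat, "weights")), ld)
ss <- read_sumstats(file.path(dat, "gwas.sumstats"))
res <- fread("results/twas_results.tsv")

sig <- res[TW_SIG == TRUE]
message("colocalizing ", nrow(sig), " significant feature(s)")
n_eqtl <- 500   # expression panel size assumed for the reconstruction

cl <- rbindlist(lapply(sig$FEATURE_ID, function(fid) {
  i <- match(fid, panel$features$feature_id)
  h <- harmonize_alleles(ss, panel$weights[[i]], ld)
  if (is.null(h)) return(NULL)
  pp <- coloc_feature(h, n_gwas = ss$n[1], n_eqtl = n_eqtl,
                      cis_h2 = panel$features$cis_h2[i])
  data.table(FEATURE_ID = fid, NSNPS = attr(pp, "nsnps"),
             PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4],
             PP4 = pp[5], BEST_MODEL = paste0("H", attr(pp, "best")))
}))
if (nrow(cl) > 0) {
  message(sprintf("model H4 (shared causal variant) preferred for %d/%d features",
                  sum(cl$BEST_MODEL == "H4"), nrow(cl)))
}
fwrite(cl, "results/coloc.tsv", sep = "\t")
message("wrote results/coloc.tsv")
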