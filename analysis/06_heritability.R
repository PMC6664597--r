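#!/usr/bin/env Rscript
# TWAS-weighted stratified LD score regression: total SNP heritability, the
# component mediated by predicted expression, liability-scale conversion,
# and the proportion of heritability captured by the weight panels.

suppressMessages({ library(sumtwas); library(data.table) })

dat <- "results/data"
ld <- read_ld_bundle(file.path(dat, "ld"))
panel <- assign_panel_blocks(read_weight_bundle(file.path(dat, "weights")), ld)
ss <- read_sumstats(file.path(dat, "gwas.sumstats"))
truth <- fread(file.path(dat, "truth_features.tsv"))

# prevalence 1.2% in the population, 39.65% cases in the GWAS sample
h2 <- twas_h2(ss, panel, ld, prevalence = 0.012, sample_prev = 0.3965,
              n_jackknife_blocks = 40)
print(h2)

true_med <- sum(truth$alpha^2)
message(sprintf("true mediated h2 (sum alpha^2) = %.4f; estimated %.4f (SE %.4f)",
                true_med, h2[category == "twas", h2_obs],
                h2[category == "twas", se]))
message(sprintf("proportion of SNP heritability captured by predicted expression: %.1f%%",
                h2[category == "twas", proportion_pct]))

out <- data.table(CATEGORY = h2$category, H2_OBS = h2$h2_obs,
                  H2_LIAB = h2$h2_liab, SE = h2$se,
                  INTERCEPT = h2$intercept,
                  PROPORTION_PCT = h2$proportion_pct)
fwrite(out, "results/heritability.tsv", sep = "\t")
message("wrote results/heritability.tsv")
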