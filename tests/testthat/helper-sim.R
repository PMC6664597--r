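# small shared fixtures, rebuilt in code at test time

small_study <- function(seed = 11, n_blocks = 5, snps_per_block = 50,
                        ar_rho = 0.8, n_features = 30, sparsity = 0.1,
                        cis_h2 = 0.2) {
  ld <- simulate_ld_blocks(n_blocks, snps_per_block, ar_rho, seed = seed)
  panel <- simulate_weight_panel(ld, n_features, sparsity, cis_h2,
                                 seed = seed + 1)
  list(ld = ld, panel = panel)
}

null_sumstats <- function(ld, panel, n_gwas = 46350, seed = NULL) {
  simulate_gwas_sumstats(ld, panel, rep(0, nrow(panel$features)),
                         direct_effect_sd = 0, n_gwas = n_gwas, seed = seed)
}

# AR(1) correlation matrix
ar1 <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), `-`))
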