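# data.table NSE column names used across the package
utils::globalVariables(c(
  "block", "snp", "chrom", "pos", "z", "Z", "N", "n", "feature_id",
  "region_id", "start", "stop", "pad_lo", "pad_hi", "p0", "p1", "twas_p",
  "twas_z", "tw_sig", "fdr_p", "fdr_sig", "p_one_sided", "p_two_sided",
  "bonf_sig", "category", "h2_obs", "h2_liab", "proportion_pct", ".N", "."))
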