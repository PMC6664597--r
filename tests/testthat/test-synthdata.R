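test_that("LD blocks have the AR(1) closed form and are positive definite", {
  ld0 <- simulate_ld_blocks(3, 10, 0, seed = 1)
  for (R in ld0$blocks) expect_equal(R, diag(10))

  ld9 <- simulate_ld_blocks(2, 20, 0.9, seed = 1)
  R <- ld9$blocks[[1]]
  expect_equal(R[1, 3], 0.81)
  expect_equal(R[5, 7], 0.81)
  expect_true(isSymmetric(R))
  expect_equal(diag(R), rep(1, 20))

  # eigendecomposition oracle across configurations
  for (rho in c(0, 0.3, 0.8, 0.95)) {
    ld <- simulate_ld_blocks(2, 25, rho, seed = 7)
    for (R in ld$blocks)
      expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  expect_error(simulate_ld_blocks(0, 10, 0.5), "positive")
  expect_error(simulate_ld_blocks(2, 10, 1.0), "ar_rho")
})

test_that("SNP table carries block id, position and unambiguous alleles", {
  ld <- simulate_ld_blocks(4, 15, 0.5, seed = 3)
  expect_equal(nrow(ld$snps), 60)
  expect_equal(ld$snps$block, rep(1:4, each = 15))
  expect_false(anyDuplicated(ld$snps$snp) > 0)
  amb <- paste0(ld$snps$a1, ld$snps$a2) %in% c("AT", "TA", "CG", "GC")
  expect_false(any(amb))
  # positions increase within each block
  expect_true(all(tapply(ld$snps$pos, ld$snps$block,
                         function(p) all(diff(p) > 0))))
})

test_that("weight panels hit the target predicted-expression variance", {
  st <- small_study(seed = 21)
  for (i in seq_len(nrow(st$panel$features))) {
    w <- st$panel$weights[[i]]
    b <- st$panel$features$block[i]
    idx <- match(w$snp, st$ld$snps[block == b, snp])
    R <- st$ld$blocks[[b]][idx, idx]
    expect_equal(drop(crossprod(w$weight, R %*% w$weight)), 0.2,
                 tolerance = 1e-10)
  }

  # sparsity selecting exactly one SNP
  one <- simulate_weight_panel(st$ld, 5, 1 / 50, 0.3, seed = 4)
  expect_true(all(vapply(one$weights, nrow, integer(1)) == 1L))
  # single-SNP feature: w^2 = cis_h2
  expect_equal(one$weights[[1]]$weight^2, 0.3, tolerance = 1e-12)

  expect_error(simulate_weight_panel(st$ld, 5, 1e-4, 0.2, seed = 1),
               "zero SNPs")

  # determinism
  p1 <- simulate_weight_panel(st$ld, 10, 0.1, 0.2, seed = 9)
  p2 <- simulate_weight_panel(st$ld, 10, 0.1, 0.2, seed = 9)
  expect_identical(p1, p2)
})

test_that("null GWAS summary statistics are calibrated and deterministic", {
  ld <- simulate_ld_blocks(50, 100, 0.8, seed = 31)   # 5,000 SNPs
  panel <- simulate_weight_panel(ld, 20, 0.05, 0.2, seed = 32)
  ss <- null_sumstats(ld, panel, seed = 33)
  # mean chi-square ~ 1 within 3 SE (SE ~ sqrt(2/5000), inflated by LD)
  expect_lt(abs(mean(ss$z^2) - 1), 3 * sqrt(2 / 5000) * 3)

  f1 <- tempfile(); f2 <- tempfile()
  write_sumstats(null_sumstats(ld, panel, seed = 34), f1)
  write_sumstats(null_sumstats(ld, panel, seed = 34), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a strong single-SNP feature produces the region's top |Z|", {
  ld <- simulate_ld_blocks(1, 40, 0.7, seed = 41)
  panel <- simulate_weight_panel(ld, 1, 1 / 40, 0.2, seed = 42)
  causal <- panel$weights[[1]]$snp
  set.seed(43)
  hits <- vapply(seq_len(200), function(r) {
    ss <- simulate_gwas_sumstats(ld, panel, alpha = 0.08,
                                 direct_effect_sd = 0, n_gwas = 46350)
    ss$snp[which.max(abs(ss$z))] == causal
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null marginal Z covariance converges to R per block", {
  ld <- simulate_ld_blocks(1, 5, 0.8, seed = 51)
  panel <- simulate_weight_panel(ld, 1, 0.4, 0.2, seed = 52)
  reps <- 2000
  set.seed(53)
  Z <- t(vapply(seq_len(reps), function(r)
    null_sumstats(ld, panel)$z, numeric(5)))
  expect_lt(max(abs(cov(Z) - ld$blocks[[1]])), 3 / sqrt(reps) * 3)
})

test_that("gene sets, truth table and property scores behave as declared", {
  st <- small_study(seed = 61, n_features = 50)
  gs0 <- simulate_gene_sets_and_properties(st$panel, 10, 5,
                                           enriched_effect = 0, seed = 62)
  expect_true(all(!gs0$truth$sets$enriched))
  expect_equal(nrow(gs0$truth$features), 50)
  expect_false(anyDuplicated(gs0$truth$features$feature_id) > 0)
  expect_false(anyDuplicated(gs0$truth$sets$set_id) > 0)
  expect_true(all(lengths(gs0$sets) == 5))
  expect_false(any(vapply(gs0$sets, anyDuplicated, integer(1)) > 0))

  gs1 <- simulate_gene_sets_and_properties(st$panel, 10, 5,
                                           enriched_effect = 0.01, seed = 63)
  expect_gt(sum(gs1$truth$sets$enriched), 0)
  enr_genes <- unlist(gs1$sets[gs1$truth$sets$enriched])
  expect_true(all(gs1$truth$features[gene_id %in% enr_genes,
                                     alpha_var > 0.01]))

  expect_error(simulate_gene_sets_and_properties(st$panel, 5, 50, seed = 1),
               "set_size")

  # requested property/alpha^2 correlation of zero at 2,000 genes
  big <- simulate_weight_panel(simulate_ld_blocks(100, 20, 0.5, seed = 64),
                               2000, 0.1, 0.2, seed = 65)
  gsp <- simulate_gene_sets_and_properties(big, 2, 10, prop_cor = 0,
                                           n_stages = 3, seed = 66)
  a2 <- gsp$truth$features$alpha^2
  for (s in 1:3)
    expect_lt(abs(cor(a2, gsp$properties[[sprintf("STAGE_%d", s)]])), 0.1)

  # GMT round trip preserves membership
  f <- tempfile(fileext = ".gmt")
  write_gmt(gs0$sets, f)
  expect_identical(read_gmt(f), gs0$sets)
})

test_that("the generator is a pure function of its configuration", {
  cfg <- sim_config(n_blocks = 4, snps_per_block = 30, n_features = 20,
                    n_sets = 6, set_size = 4, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
})
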