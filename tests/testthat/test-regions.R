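test_that("region clustering follows the padded-overlap rule", {
  # two genes 2.7 Mb apart with a 0.5 Mb window are independent regions
  f <- data.table::data.table(
    feature_id = c("A", "B"), chrom = 8,
    start = c(1e6, 3.7e6), stop = c(1.01e6, 3.71e6))
  r <- build_regions(f, window = 5e5)
  expect_equal(nrow(r$regions), 2)

  # 0.4 Mb apart -> one region
  f2 <- data.table::data.table(
    feature_id = c("A", "B"), chrom = 8,
    start = c(1e6, 1.4e6), stop = c(1.01e6, 1.41e6))
  r2 <- build_regions(f2, window = 5e5)
  expect_equal(nrow(r2$regions), 1)
  expect_equal(r2$regions$n_features, 2)

  # one feature -> its padded bounds
  f3 <- data.table::data.table(feature_id = "A", chrom = 1,
                               start = 2e6, stop = 2.1e6)
  r3 <- build_regions(f3, window = 5e5)
  expect_equal(r3$regions$start, 1.5e6)
  expect_equal(r3$regions$stop, 2.6e6)

  # different chromosomes never share a region
  f4 <- data.table::data.table(feature_id = c("A", "B"), chrom = c(1, 2),
                               start = c(1e6, 1e6), stop = c(1e6, 1e6))
  expect_equal(nrow(build_regions(f4)$regions), 2)
})

test_that("forward selection separates joint from marginal associations", {
  thr <- 4.25e-6
  # a single significant feature is jointly significant
  j1 <- joint_conditional_analysis("F1", 6, matrix(1), thr)
  expect_equal(j1$jointly, "F1")
  expect_equal(j1$marginally, character(0))

  # two uncorrelated significant features are both retained
  j2 <- joint_conditional_analysis(c("F1", "F2"), c(6, 5.5), diag(2), thr)
  expect_setequal(j2$jointly, c("F1", "F2"))

  # near-duplicate features (r = 0.99): exactly one survives
  C <- matrix(c(1, 0.99, 0.99, 1), 2)
  j3 <- joint_conditional_analysis(c("F1", "F2"), c(5.0, 4.9), C, thr)
  expect_equal(j3$jointly, "F1")
  expect_equal(j3$marginally, "F2")
  # 2x2 algebra oracle for the second feature's conditional z
  expect_equal(conditional_z(2, 1, c(5.0, 4.9), C),
               (4.9 - 0.99 * 5) / sqrt(1 - 0.99^2), tolerance = 1e-12)
  expect_equal(j3$trace$cond_z, 5.0)

  # jointly and marginally partition the members
  expect_setequal(c(j3$jointly, j3$marginally), c("F1", "F2"))
  expect_length(intersect(j3$jointly, j3$marginally), 0)
})

test_that("conditioning GWAS statistics on features follows the projection", {
  # uncorrelated SNP: unchanged, nothing explained
  c0 <- condition_gwas_on_features(3, 0, matrix(1), 5)
  expect_equal(c0$z_cond, 3)
  expect_equal(c0$variance_explained, 0)

  # worked single-feature example
  c1 <- condition_gwas_on_features(6, 0.9, matrix(1), 6)
  expect_equal(c1$z_cond, 1.376494403, tolerance = 1e-8)
  expect_equal(c1$variance_explained, 0.9473684211, tolerance = 1e-8)
  expect_equal(c1$variance_explained, 1 - c1$z_cond^2 / c1$z_uncond^2,
               tolerance = 1e-10)

  # SNP collinear with a single-SNP feature is fully explained
  c2 <- condition_gwas_on_features(5, 1, matrix(1), 5)
  expect_equal(c2$z_cond, 0)
  expect_equal(c2$variance_explained, 1)

  # idempotence: the conditioned score is uncorrelated with the features,
  # so conditioning it again leaves it unchanged
  c3 <- condition_gwas_on_features(c1$z_cond, 0, matrix(1), 6)
  expect_equal(c3$z_cond, c1$z_cond)

  # vectorized over SNPs, multi-feature
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  cm <- condition_gwas_on_features(c(4, 0), rbind(c(0.3, 0.2), c(0, 0)),
                                   C, c(5, 4))
  expect_equal(cm$z_cond[2], 0)
  expect_true(is.na(cm$variance_explained[2]))
})

test_that("the omnibus test pools panels with the right degrees of freedom", {
  # one panel reduces to the two-sided test
  o1 <- omnibus_test(2, matrix(1))
  expect_equal(o1$stat, 4)
  expect_equal(o1$df, 1)
  expect_equal(o1$p, 0.0455002639, tolerance = 1e-9)
  # df = 1 reproduces the per-feature two-sided p exactly, any z
  for (z in c(-3.2, 0.4, 4.6))
    expect_equal(omnibus_test(z, matrix(1))$p, 2 * pnorm(-abs(z)),
                 tolerance = 1e-12)

  # two independent panels
  o2 <- omnibus_test(c(2, 2), diag(2))
  expect_equal(o2$stat, 8)
  expect_equal(o2$df, 2)
  expect_equal(o2$p, exp(-4), tolerance = 1e-10)

  # perfectly correlated panels are rank deficient
  o3 <- omnibus_test(c(3, 3), matrix(1, 2, 2))
  expect_equal(o3$df, 1)
  expect_equal(o3$stat, 9, tolerance = 1e-10)
})

test_that("the SNP-wise mean test is exact for one SNP and calibrated", {
  ld <- simulate_ld_blocks(1, 1, 0, seed = 201)
  ss <- data.table::data.table(snp = ld$snps$snp, z = 2)
  g <- list(chrom = ld$snps$chrom[1], start = ld$snps$pos[1],
            stop = ld$snps$pos[1])
  r <- snpwise_mean_region_test(g, ss, ld)
  expect_equal(r$stat, 4)
  expect_equal(r$p, 0.0455002639, tolerance = 1e-9)

  # missing window -> skipped with a log message
  g2 <- list(chrom = 99, start = 1, stop = 2)
  expect_message(expect_null(snpwise_mean_region_test(g2, ss, ld)),
                 "skipped")

  # m independent SNPs: null mean(T) = 1, var(T) = 2/m
  m <- 20
  set.seed(202)
  Tstat <- replicate(10000, mean(rnorm(m)^2))
  expect_lt(abs(mean(Tstat) - 1), 4 * sqrt(2 / m / 10000))
  expect_lt(abs(var(Tstat) - 2 / m), 0.15 * 2 / m)

  # type-I error on a simulated null GWAS
  ldc <- simulate_ld_blocks(100, 60, 0.8, seed = 203)
  pc <- simulate_weight_panel(ldc, 500, 5 / 60, 0.2, seed = 204)
  ssc <- null_sumstats(ldc, pc, seed = 205)
  pvals <- vapply(seq_len(500), function(i) {
    g <- pc$features[i]
    snpwise_mean_region_test(list(chrom = g$chrom, start = g$start,
                                  stop = g$stop), ssc, ldc)$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.035)
  expect_lte(mean(pvals < 0.05), 0.065)
})

test_that("the region report merges stages into a Table-2-shaped summary", {
  ld <- simulate_ld_blocks(6, 60, 0.8, seed = 211)
  panel <- simulate_weight_panel(ld, 40, 0.1, 0.2, seed = 212)
  alpha <- rep(0, 40); alpha[c(3, 17)] <- 0.05
  ss <- simulate_gwas_sumstats(ld, panel, alpha, 0, 46350, seed = 213)
  res <- suppressMessages(twas_scan(ss, panel, ld, threshold_p = 4.25e-6))
  fc <- feature_correlations(panel, ld)
  rep <- suppressMessages(
    region_report(res, ss, panel, ld, fc, threshold = 4.25e-6))
  expect_true(nrow(rep) >= 1)
  expect_true(all(c("location", "minp_twas", "minp_gwas", "minp_regiontest",
                    "var_explained_pct", "jointly_sig", "marginally_sig")
                  %in% names(rep)))
  expect_true(all(rep$minp_twas < 4.25e-6))
  expect_true(all(nchar(rep$jointly_sig) > 0))
})
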