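test_that("the association-Z transform is the inverse-normal of p", {
  expect_equal(association_z_transform(0.5), 0)
  expect_equal(association_z_transform(0.05), 1.644853627, tolerance = 1e-8)
  # monotone decreasing in p
  p <- c(0.9, 0.5, 0.1, 1e-4)
  expect_true(all(diff(association_z_transform(p)) > 0))
  # boundaries stay finite
  z1 <- association_z_transform(1)
  expect_true(is.finite(z1) && z1 < -5)
  expect_warning(z0 <- association_z_transform(0), "clamped")
  expect_true(is.finite(z0) && z0 > 5)
  expect_error(association_z_transform(-0.1), "\\[0, 1\\]")
})

test_that("the relatedness matrix is squared, PSD and unit diagonal", {
  st <- small_study(seed = 401)
  fc <- feature_correlations(st$panel, st$ld)
  rel <- build_feature_relatedness(fc)
  C <- as.matrix(fc)
  expect_equal(diag(rel$K), setNames(rep(1, ncol(C)), colnames(C)))
  # K is the squared correlation where no clipping was needed
  expect_equal(rel$K, C^2, tolerance = 1e-8)
  expect_gte(min(rel_lambda(rel)), 0)

  # mutually uncorrelated features -> identity
  rel_id <- build_feature_relatedness(diag(5))
  expect_equal(unname(rel_id$K), diag(5))

  # duplicated feature pair -> all-ones 2x2 block, still PSD after clipping
  Cdup <- matrix(c(1, 1, 1, 1), 2)
  rel_dup <- build_feature_relatedness(Cdup)
  expect_equal(unname(rel_dup$K), matrix(1, 2, 2), tolerance = 1e-10)
  expect_gte(min(rel_lambda(rel_dup)), -1e-8)
})

test_that("with K = identity the mixed model reduces to OLS exactly", {
  set.seed(402)
  n <- 300
  z <- rnorm(n)
  s <- as.numeric(seq_len(n) %in% sample(n, 40))
  rel <- build_feature_relatedness(diag(n))
  fit <- competitive_set_test(z, s, rel, set_id = "S")

  ols <- summary(lm(z ~ s))$coefficients
  expect_equal(fit$beta, ols["s", "Estimate"], tolerance = 1e-4)
  expect_equal(fit$se, ols["s", "Std. Error"], tolerance = 1e-4)
  expect_equal(fit$p_one_sided,
               pt(ols["s", "t value"], n - 2, lower.tail = FALSE),
               tolerance = 1e-4)
})

test_that("the set test honors its invariances", {
  st <- small_study(seed = 403)
  fc <- feature_correlations(st$panel, st$ld)
  rel <- build_feature_relatedness(fc)
  ss <- null_sumstats(st$ld, st$panel, seed = 404)
  res <- suppressMessages(twas_scan(ss, st$panel, st$ld))
  z <- association_z_transform(res$twas_p)
  ord <- match(rel$feature_id, res$feature_id)
  z <- z[ord]
  s <- seq_along(z) %in% c(2, 5, 9, 14, 20)

  base <- competitive_set_test(z, s, rel)
  # location invariance: shifting all z moves only the intercept
  shift <- competitive_set_test(z + 3, s, rel)
  expect_equal(shift$beta, base$beta, tolerance = 1e-6)
  expect_equal(shift$p_one_sided, base$p_one_sided, tolerance = 1e-6)

  # degenerate sets are rejected
  expect_error(competitive_set_test(z, rep(TRUE, length(z)), rel),
               "degenerate")
  expect_error(competitive_set_test(z, rep(FALSE, length(z)), rel),
               "degenerate")
})

test_that("an enriched set is detected and null sets are not", {
  ld <- simulate_ld_blocks(30, 40, 0.7, seed = 405)
  panel <- simulate_weight_panel(ld, 300, 0.1, 0.2, seed = 406)
  gs <- simulate_gene_sets_and_properties(panel, 20, 25,
                                          enriched_effect = 4e-3,
                                          gene_effect_sd = 1e-3,
                                          n_enriched = 1, seed = 407)
  ss <- simulate_gwas_sumstats(ld, panel, gs$alpha, 0, 46350, seed = 408)
  res <- suppressMessages(twas_scan(ss, panel, ld))
  fc <- feature_correlations(panel, ld)
  rel <- build_feature_relatedness(fc)
  z <- association_z_transform(res$twas_p)[match(rel$feature_id,
                                                 res$feature_id)]
  gid <- res$gene_id[match(rel$feature_id, res$feature_id)]
  enr <- suppressMessages(enrichment_gene_sets(z, gid, gs$sets, rel))
  hit <- gs$truth$sets[enriched == TRUE, set_id]
  expect_lt(enr[set_id == hit, p_one_sided], 0.05)
  expect_equal(nrow(enr), 20)
  expect_true(all(enr$p_one_sided > 0 & enr$p_one_sided <= 1))
})

test_that("property gradients track a perfect predictor and skip constants", {
  set.seed(409)
  n <- 200
  rel <- build_feature_relatedness(diag(n))
  z <- rnorm(n)
  scores <- cbind(S1 = z, S2 = rnorm(n), S3 = rep(1, n))
  expect_message(res <- property_gradient_test(z, scores, rel), "skipped")
  expect_equal(nrow(res), 2)
  expect_gt(res[stage == "S1", beta], 0)
  expect_lt(res[stage == "S1", p_two_sided], 1e-10)
  expect_true(res[stage == "S1", bonf_sig])

  # permuted scores are calibrated (null column p uniform-ish over reps)
  set.seed(410)
  pvals <- replicate(200, {
    property_gradient_test(z, cbind(S = sample(z)), rel)$p_two_sided
  })
  expect_gt(ks.test(pvals, punif)$p.value, 0.01)
})

test_that("panel enrichment flags the inflated weight set", {
  ld <- simulate_ld_blocks(30, 40, 0.7, seed = 411)
  pA <- simulate_weight_panel(ld, 150, 0.1, 0.2, seed = 412,
                              panel_id = "PANEL_A")
  pB <- simulate_weight_panel(ld, 150, 0.1, 0.2, seed = 413,
                              panel_id = "PANEL_B")
  panel <- structure(list(
    features = rbind(pA$features, pB$features),
    weights = c(pA$weights, pB$weights)), class = "weight_panel")
  set.seed(414)
  alpha <- c(rnorm(150, 0, 0.01), rnorm(150, 0, 0.002))  # A inflated
  ss <- simulate_gwas_sumstats(ld, panel, alpha, 0, 46350, seed = 415)
  res <- suppressMessages(twas_scan(ss, panel, ld))
  fc <- feature_correlations(panel, ld)
  rel <- build_feature_relatedness(fc)
  ord <- match(rel$feature_id, res$feature_id)
  z <- association_z_transform(res$twas_p)[ord]
  labs <- res$panel[ord]
  enr <- weight_set_enrichment(z, labs, rel)
  expect_gt(enr[set_id == "PANEL_A", beta], 0)
  expect_lt(enr[set_id == "PANEL_B", beta], 0)

  expect_error(weight_set_enrichment(z, labs, rel, restrict_to = "PANEL_A"),
               "fewer than two")
})
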