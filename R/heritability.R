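#' Per-SNP LD scores
#'
#' `l_j = sum_k r_jk^2` over the reference SNPs of the SNP's block (the self
#' term is included, so `l_j >= 1`).
#'
#' @param ld an `ld_reference`
#' @return data.table with columns snp, l2_total, aligned to `ld$snps`
#' @export
ld_scores <- function(ld) {
  l2 <- unlist(lapply(ld$blocks, function(R) colSums(R^2)),
               use.names = FALSE)
  data.table::data.table(snp = ld$snps$snp, l2_total = l2)
}

#' Predicted-expression-weighted LD scores
#'
#' For each SNP j, `l_expr_j = sum_f rho(j, f)^2` where
#' `rho(j, f) = (R w_f)_j / sqrt(w_f' R w_f)` is the correlation between the
#' SNP and feature f's predicted expression. Additive over features; SNPs in
#' blocks without any feature get 0.
#'
#' @param panel a `weight_panel` (aligned to `ld`)
#' @param ld an `ld_reference`
#' @return data.table with columns snp, l2_expr, aligned to `ld$snps`
#' @export
predicted_expression_ld_scores <- function(panel, ld) {
  l2e <- numeric(nrow(ld$snps))
  block_rows <- split(seq_len(nrow(ld$snps)), ld$snps$block)
  for (i in seq_len(nrow(panel$features))) {
    b <- panel$features$block[i]
    rows <- block_rows[[as.character(b)]]
    wtab <- panel$weights[[i]]
    idx <- match(wtab$snp, ld$snps$snp[rows])
    rho <- snp_feature_correlation(wtab$weight, ld$blocks[[b]], idx)
    l2e[rows] <- l2e[rows] + rho^2
  }
  data.table::data.table(snp = ld$snps$snp, l2_expr = l2e)
}

#' Stratified LD score regression
#'
#' Weighted least-squares fit of `E[chi2_j] = 1 + N sum_c tau_c l_cj` with a
#' free intercept, regression weights `1 / max(l_weight, 1)` (single pass),
#' and standard errors by leave-one-block-out jackknife over contiguous SNP
#' blocks. The heritability of category c is `M_c tau_c`; the total is their
#' sum.
#'
#' @param chi2 per-SNP GWAS chi-square (`z^2`)
#' @param ldscores numeric matrix of LD score columns (one per category) or
#'   a vector for a single category
#' @param N GWAS sample size
#' @param M per-category normalizer: the number of units whose effects the
#'   category's tau averages over (SNP count for the total category, feature
#'   count for a predicted-expression category)
#' @param n_jackknife_blocks number of contiguous jackknife blocks
#' @param weight_ld LD scores used for the regression weights (defaults to
#'   the first column)
#' @param het_weights when `TRUE` (default) a second pass reweights each SNP
#'   by `1 / (2 * fitted^2)` in addition to `1 / l`, downweighting the
#'   heavy-tailed chi-squares at high-signal SNPs (standard LDSC practice);
#'   `FALSE` keeps the single-pass `1 / max(l, 1)` weights
#' @return object of class `ldsc_fit`: data.table `$categories` (category,
#'   tau, h2_obs, se), plus `$h2_total`, `$h2_total_se`, `$intercept`,
#'   `$intercept_se`, `$n_snps`
#' @export
ldsc_fit <- function(chi2, ldscores, N, M, n_jackknife_blocks = 200L,
                     weight_ld = NULL, het_weights = TRUE) {
  if (het_weights) {
    L <- as.matrix(ldscores)
    f1 <- ldsc_fit(chi2, L, N, M, n_jackknife_blocks, weight_ld,
                   het_weights = FALSE)
    fitted <- pmax(f1$intercept + drop((N * L) %*% f1$categories$tau), 1e-2)
    wld <- pmax(weight_ld %||% L[, 1], 1) * (2 * fitted^2)
    return(ldsc_fit(chi2, L, N, M, n_jackknife_blocks, weight_ld = wld,
                    het_weights = FALSE))
  }
  L <- as.matrix(ldscores)
  n <- length(chi2)
  C <- ncol(L)
  if (length(M) != C) stop_input("M must have one entry per category")
  if (n_jackknife_blocks < 2L) stop_input("need at least 2 jackknife blocks")
  if (any(apply(L, 2, var) == 0))
    stop_input("degenerate regression: an LD score column has zero variance")
  cats <- colnames(L) %||% sprintf("cat%d", seq_len(C))
  wld <- weight_ld %||% L[, 1]
  wt <- 1 / pmax(wld, 1)
  X <- cbind(intercept = 1, N * L)
  p <- ncol(X)

  blk <- as.integer(cut(seq_len(n), n_jackknife_blocks, labels = FALSE))
  A <- array(0, c(p, p, n_jackknife_blocks))
  bvec <- matrix(0, p, n_jackknife_blocks)
  for (b in seq_len(n_jackknife_blocks)) {
    rows <- which(blk == b)
    Xb <- X[rows, , drop = FALSE] * wt[rows]
    A[, , b] <- crossprod(X[rows, , drop = FALSE], Xb)
    bvec[, b] <- crossprod(Xb, chi2[rows])
  }
  Atot <- apply(A, c(1, 2), sum)
  btot <- rowSums(bvec)
  coef_full <- tryCatch(solve(Atot, btot), error = function(e)
    stop_input("degenerate regression: collinear LD score columns"))

  # leave-one-block-out estimates of (intercept, tau_1..tau_C)
  theta <- matrix(0, n_jackknife_blocks, p)
  for (b in seq_len(n_jackknife_blocks))
    theta[b, ] <- solve(Atot - A[, , b], btot - bvec[, b])
  jack_se <- function(stat_fun) {
    v <- apply(theta, 1, stat_fun)
    sqrt((n_jackknife_blocks - 1) / n_jackknife_blocks *
           sum((v - mean(v))^2))
  }

  tau <- coef_full[-1]
  h2 <- M * tau
  h2_se <- vapply(seq_len(C), function(ci)
    jack_se(function(th) M[ci] * th[ci + 1]), numeric(1))
  structure(list(
    categories = data.table::data.table(category = cats, tau = tau,
                                        h2_obs = h2, se = h2_se),
    h2_total = sum(h2),
    h2_total_se = jack_se(function(th) sum(M * th[-1])),
    intercept = coef_full[1],
    intercept_se = jack_se(function(th) th[1]),
    n_snps = n, n_blocks = n_jackknife_blocks),
    class = "ldsc_fit")
}

#' Observed-scale to liability-scale heritability
#'
#' `h2_liab = h2_obs * K^2 (1 - K)^2 / (P (1 - P) phi(t)^2)` with
#' `t = qnorm(1 - K)`, for population prevalence `K` and sample (case)
#' proportion `P`.
#'
#' @param h2_obs observed-scale heritability
#' @param K_prevalence population prevalence, in (0, 1)
#' @param P_sample sample case proportion, in (0, 1)
#' @return liability-scale heritability
#' @export
liability_scale_transform <- function(h2_obs, K_prevalence, P_sample) {
  K <- K_prevalence; P <- P_sample
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop_input("prevalences must lie strictly in (0, 1)")
  t <- qnorm(1 - K)
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(t)^2)
}

#' Proportion of SNP heritability captured by predicted expression
#'
#' @param h2_twas_liab TWAS-weighted (mediated) heritability
#' @param h2_total_liab total SNP heritability on the same scale
#' @return percentage, `100 * h2_twas / h2_total`; values above 100 are
#'   reported with a warning, never clamped
#' @export
twas_h2_proportion <- function(h2_twas_liab, h2_total_liab) {
  if (h2_total_liab <= 0) stop_input("total heritability must be positive")
  pct <- 100 * h2_twas_liab / h2_total_liab
  if (pct > 100)
    warning("TWAS heritability exceeds total heritability (", round(pct, 1),
            "%)")
  pct
}

#' TWAS-weighted heritability partition for one study
#'
#' Computes total and predicted-expression LD scores, fits the two-category
#' stratified LD score regression (the total heritability is the sum over
#' the two categories of `M_c tau_c`), optionally converts both estimates to
#' the liability scale, and reports the proportion of SNP heritability
#' captured by predicted expression.
#'
#' @param sumstats GWAS summary statistics (snp, z, n)
#' @param panel a `weight_panel`
#' @param ld an `ld_reference`
#' @param prevalence population prevalence (optional; liability conversion
#'   skipped when `NULL`)
#' @param sample_prev sample case proportion (required with `prevalence`)
#' @param n_jackknife_blocks jackknife blocks (default 200)
#' @return data.table with rows `total` and `twas`: h2_obs, h2_liab, se,
#'   intercept, proportion_pct (on the twas row)
#' @export
twas_h2 <- function(sumstats, panel, ld, prevalence = NULL,
                    sample_prev = NULL, n_jackknife_blocks = 200L) {
  l2 <- ld_scores(ld)
  l2e <- predicted_expression_ld_scores(panel, ld)
  z <- sumstats$z[match(ld$snps$snp, sumstats$snp)]
  keep <- is.finite(z)
  N <- sumstats$n[1]
  L <- cbind(total = l2$l2_total[keep], expr = l2e$l2_expr[keep])
  fit <- ldsc_fit(z[keep]^2, L, N,
                  M = c(sum(keep), nrow(panel$features)),
                  n_jackknife_blocks = n_jackknife_blocks)
  h2_twas <- fit$categories[category == "expr", h2_obs]
  h2_twas_se <- fit$categories[category == "expr", se]
  out <- data.table::data.table(
    category = c("total", "twas"),
    h2_obs = c(fit$h2_total, h2_twas),
    se = c(fit$h2_total_se, h2_twas_se),
    intercept = fit$intercept)
  if (!is.null(prevalence)) {
    if (is.null(sample_prev))
      stop_input("sample_prev is required for the liability conversion")
    out[, h2_liab := liability_scale_transform(h2_obs, prevalence,
                                               sample_prev)]
  } else out[, h2_liab := NA_real_]
  prop <- twas_h2_proportion(h2_twas, fit$h2_total)
  out[, proportion_pct := c(NA_real_, prop)]
  out[]
}
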