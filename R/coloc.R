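#' Wakefield log approximate Bayes factor
#'
#' For a SNP with association Z score `z` and sampling variance `v`, and a
#' prior variance `W` on the standardized effect, the approximate Bayes
#' factor against the point null is `sqrt(1 - r) * exp(z^2 r / 2)` with
#' `r = W / (W + v)`. Returned on the natural-log scale, which is stable for
#' |z| well beyond 40.
#'
#' @param z association Z score(s)
#' @param v sampling variance of the effect estimate (e.g. `1/N` for a
#'   standardized trait)
#' @param W prior variance of the effect (default `0.15^2`)
#' @return numeric vector of log ABFs
#' @export
wakefield_log_abf <- function(z, v, W = 0.15^2) {
  if (any(v <= 0)) stop_input("sampling variance v must be positive")
  if (any(W < 0)) stop_input("prior variance W must be non-negative")
  r <- W / (W + v)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Colocalization posterior probabilities (single causal variant per trait)
#'
#' Combines per-SNP log ABFs for two traits over the same SNPs into
#' posterior probabilities of the five hypotheses: H0 no association, H1/H2
#' association for one trait only, H3 two distinct causal SNPs, H4 one
#' shared causal SNP. All sums are computed in log space.
#'
#' @param labf1 log ABFs for trait 1 (GWAS), one per SNP
#' @param labf2 log ABFs for trait 2 (expression), same SNP order
#' @param p1 prior probability a SNP is causal for trait 1
#' @param p2 prior probability a SNP is causal for trait 2
#' @param p12 prior probability a SNP is causal for both
#' @return object of class `coloc_result`: named numeric vector pp0..pp4
#'   (sums to 1), with attributes `nsnps` and `best`
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(labf1)
  if (n == 0L) stop_input("at least one SNP is required")
  if (length(labf2) != n) stop_input("labf vectors must have equal length")
  if (any(c(p1, p2, p12) <= 0) || any(c(p1, p2, p12) >= 1))
    stop_input("priors must lie in (0, 1)")
  if (p12 > min(p1, p2)) stop_input("p12 must not exceed min(p1, p2)")
  ls1 <- logsumexp(labf1)
  ls2 <- logsumexp(labf2)
  ls12 <- logsumexp(labf1 + labf2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + ls1,
    h2 = log(p2) + ls2,
    # ordered distinct pairs: sum_i sum_{j != i} ABF1_i ABF2_j
    h3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
    h4 = log(p12) + ls12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("pp", 0:4)
  structure(pp, nsnps = n, best = which.max(pp) - 1L,
            class = "coloc_result")
}

#' Colocalize one feature's expression signal with the GWAS signal
#'
#' Runs Wakefield-ABF colocalization over the feature's harmonized weight
#' SNPs. The GWAS side uses the observed marginal Z with `v = 1/N`. The
#' expression side is reconstructed from the weights: the marginal
#' expression association of SNP j is implied by the SNP's correlation with
#' predicted expression, `z_e = sqrt(N_eqtl) * rho_j * sqrt(cis_h2)` with
#' `rho = Rw / sqrt(w'Rw)` (an interpretation; the expression panel's own
#' marginal statistics are not part of a weight bundle).
#'
#' @param harmonized output of [harmonize_alleles()] for the feature
#' @param n_gwas GWAS sample size
#' @param n_eqtl expression panel sample size
#' @param cis_h2 the feature's cis heritability
#' @param p1,p2,p12 priors, see [coloc_posteriors()]
#' @param W prior effect variance
#' @return a `coloc_result`
#' @export
coloc_feature <- function(harmonized, n_gwas, n_eqtl, cis_h2,
                          p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.15^2) {
  h <- harmonized
  keep <- seq_along(h$w)
  Rsub <- h$R
  rho <- drop(Rsub %*% h$w) / sqrt(drop(crossprod(h$w, Rsub %*% h$w)))
  z_e <- sqrt(n_eqtl) * rho * sqrt(cis_h2)
  labf1 <- wakefield_log_abf(h$z, 1 / n_gwas, W)
  labf2 <- wakefield_log_abf(z_e, 1 / n_eqtl, W)
  coloc_posteriors(labf1, labf2, p1, p2, p12)
}

#' Colocalization discrimination experiment on synthetic regions
#'
#' Repeatedly simulates a two-trait region under either a shared-causal or a
#' distinct-causal (linkage-equilibrium) architecture and records how often
#' the diagnostic posterior (pp4 for shared, pp3 for distinct) exceeds
#' `pp_cut`. The causal SNP's marginal Z is drawn around `z_causal`, the
#' strength of an unambiguous genome-wide-significant locus.
#'
#' @param scenario `"shared"` (one causal SNP for both traits) or
#'   `"distinct"` (one causal SNP per trait, mutually in linkage
#'   equilibrium)
#' @param n_reps number of simulated regions
#' @param m SNPs per region
#' @param rho AR(1) LD within the region
#' @param n sample size per trait
#' @param z_causal expected marginal Z at the causal SNP
#' @param pp_cut posterior cutoff counted as a confident call
#' @param seed optional integer seed
#' @return list with `rate` (fraction of confident correct calls), `n_reps`
#' @export
coloc_discrimination_rate <- function(scenario = c("shared", "distinct"),
                                      n_reps = 100, m = 40, rho = 0.5,
                                      n = 50000, z_causal = 8,
                                      pp_cut = 0.9, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  R <- rho^abs(outer(seq_len(m), seq_len(m), `-`))
  U <- chol(R)
  b <- z_causal / sqrt(n)
  hits <- vapply(seq_len(n_reps), function(r) {
    if (scenario == "shared") {
      k <- sample.int(m, 1)
      beta1 <- beta2 <- numeric(m)
      beta1[k] <- b; beta2[k] <- b
    } else {
      # causal SNPs far enough apart that their LD is numerically zero
      beta1 <- numeric(m); beta2 <- numeric(m)
      beta1[ceiling(m / 8)] <- b; beta2[m - ceiling(m / 8)] <- b
    }
    z1 <- simulate_region_z(R, beta1, n, U)
    z2 <- simulate_region_z(R, beta2, n, U)
    pp <- coloc_posteriors(wakefield_log_abf(z1, 1 / n),
                           wakefield_log_abf(z2, 1 / n))
    target <- if (scenario == "shared") pp["pp4"] else pp["pp3"]
    target > pp_cut
  }, logical(1))
  list(rate = mean(hits), n_reps = n_reps)
}
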