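#' Harmonize a feature's weights with summary statistics and the LD reference
#'
#' Orients everything into the LD reference allele frame: weights and Z
#' scores at SNPs whose a1/a2 are swapped relative to the reference are sign
#' flipped; SNPs with mismatching alleles, strand-ambiguous SNPs (A/T, C/G)
#' and SNPs absent from the summary statistics or the reference are dropped
#' and counted.
#'
#' @param sumstats data.table with columns snp, a1, a2, z (e.g. from
#'   [read_sumstats()] or [simulate_gwas_sumstats()])
#' @param feature_weights data.table with columns snp, a1, a2, weight for one
#'   feature
#' @param ld an `ld_reference`
#' @return `NULL` if no SNP survives (the caller should skip the feature),
#'   otherwise a list with `snp`, `w`, `z`, `R` (aligned weight/Z vectors and
#'   LD submatrix), `block`, `idx` (positions within the block) and `dropped`
#'   (named counts: missing, ambiguous, mismatch)
#' @export
harmonize_alleles <- function(sumstats, feature_weights, ld) {
  fw <- data.table::as.data.table(feature_weights)
  dropped <- c(missing = 0L, ambiguous = 0L, mismatch = 0L)

  ref <- ld$snps[match(fw$snp, snp)]
  miss <- is.na(ref$snp)
  dropped["missing"] <- dropped["missing"] + sum(miss)
  fw <- fw[!miss]; ref <- ref[!miss]
  if (nrow(fw) == 0L) return(NULL)

  amb <- (ref$a1 == "A" & ref$a2 == "T") | (ref$a1 == "T" & ref$a2 == "A") |
         (ref$a1 == "C" & ref$a2 == "G") | (ref$a1 == "G" & ref$a2 == "C")
  dropped["ambiguous"] <- dropped["ambiguous"] + sum(amb)
  fw <- fw[!amb]; ref <- ref[!amb]
  if (nrow(fw) == 0L) return(NULL)

  same_w <- fw$a1 == ref$a1 & fw$a2 == ref$a2
  swap_w <- fw$a1 == ref$a2 & fw$a2 == ref$a1
  bad <- !(same_w | swap_w)
  dropped["mismatch"] <- dropped["mismatch"] + sum(bad)
  fw <- fw[!bad]; ref <- ref[!bad]; same_w <- same_w[!bad]
  if (nrow(fw) == 0L) return(NULL)
  w <- fw$weight * ifelse(same_w, 1, -1)

  ss <- sumstats[match(fw$snp, snp)]
  miss <- is.na(ss$snp) | !is.finite(ss$z)
  dropped["missing"] <- dropped["missing"] + sum(miss)
  fw <- fw[!miss]; ref <- ref[!miss]; ss <- ss[!miss]; w <- w[!miss]
  if (nrow(fw) == 0L) return(NULL)
  same_z <- ss$a1 == ref$a1 & ss$a2 == ref$a2
  swap_z <- ss$a1 == ref$a2 & ss$a2 == ref$a1
  bad <- !(same_z | swap_z)
  dropped["mismatch"] <- dropped["mismatch"] + sum(bad)
  fw <- fw[!bad]; ref <- ref[!bad]; ss <- ss[!bad]; w <- w[!bad]
  same_z <- same_z[!bad]
  if (nrow(fw) == 0L) return(NULL)
  z <- ss$z * ifelse(same_z, 1, -1)

  blocks <- unique(ref$block)
  if (length(blocks) != 1L)
    stop_input("feature spans more than one LD block")
  b <- blocks[1]
  block_snps <- ld$snps[block == b, snp]
  idx <- match(ref$snp, block_snps)
  R <- ld$blocks[[b]][idx, idx, drop = FALSE]
  list(snp = ref$snp, w = w, z = z, R = R, block = b, idx = idx,
       dropped = dropped)
}

#' TWAS association statistic for one feature
#'
#' `Z_TWAS = w'z / sqrt(w'Rw)`: the association of genetically predicted
#' expression with the trait, computed from marginal GWAS Z scores `z`, SNP
#' weights `w` and the LD matrix `R`. Invariant to positive rescaling of `w`.
#'
#' @param w aligned weight vector
#' @param z aligned marginal Z vector
#' @param R LD submatrix for the same SNPs
#' @return list with `z` (Z_TWAS), `p` (two-sided), `n_snps`
#' @export
twas_association <- function(w, z, R) {
  qf <- drop(crossprod(w, R %*% w))
  if (!is.finite(qf) || qf <= 1e-10)
    stop_input("degenerate feature: predicted-expression variance w'Rw <= 1e-10")
  zt <- sum(w * z) / sqrt(qf)
  list(z = zt, p = z_to_p(zt), n_snps = length(w))
}

#' TWAS scan over a weight panel
#'
#' Harmonizes and tests every feature of a panel against one set of GWAS
#' summary statistics; attaches Benjamini-Hochberg FDR-adjusted p values and,
#' when a threshold is supplied, the transcriptome-wide significance flag.
#'
#' @param sumstats GWAS summary statistics (snp, a1, a2, z, n)
#' @param panel a `weight_panel`
#' @param ld an `ld_reference`
#' @param fdr_q FDR level for the `fdr_sig` flag
#' @param threshold_p optional transcriptome-wide significance threshold
#'   (e.g. from [permutation_significance_threshold()])
#' @return data.table with one row per tested feature: panel, feature_id,
#'   gene_id, chrom, p0, p1, n_snps, twas_z, twas_p, fdr_p, fdr_sig
#'   (and tw_sig when `threshold_p` is given)
#' @export
twas_scan <- function(sumstats, panel, ld, fdr_q = 0.05, threshold_p = NULL) {
  feats <- panel$features
  out <- vector("list", nrow(feats))
  n_skipped <- 0L
  drop_tot <- c(missing = 0L, ambiguous = 0L, mismatch = 0L)
  for (i in seq_len(nrow(feats))) {
    h <- harmonize_alleles(sumstats, panel$weights[[i]], ld)
    if (is.null(h)) { n_skipped <- n_skipped + 1L; next }
    drop_tot <- drop_tot + h$dropped
    a <- tryCatch(twas_association(h$w, h$z, h$R), error = function(e) NULL)
    if (is.null(a)) { n_skipped <- n_skipped + 1L; next }
    out[[i]] <- data.table::data.table(
      panel = feats$panel_id[i], feature_id = feats$feature_id[i],
      gene_id = feats$gene_id[i], chrom = feats$chrom[i],
      p0 = feats$start[i], p1 = feats$stop[i],
      n_snps = a$n_snps, twas_z = a$z, twas_p = a$p)
  }
  if (n_skipped > 0L || any(drop_tot > 0L))
    message("twas_scan: skipped ", n_skipped, " feature(s); dropped SNPs: ",
            paste(names(drop_tot), drop_tot, sep = "=", collapse = ", "))
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) return(res)
  fdr <- bh_fdr(res$twas_p, q = fdr_q)
  res[, `:=`(fdr_p = fdr$adjusted, fdr_sig = fdr$discovery)]
  if (!is.null(threshold_p)) res[, tw_sig := twas_p < threshold_p]
  res[]
}

#' Pairwise correlations of predicted expression between features
#'
#' `r_ij = w_i' R w_j / sqrt((w_i'Rw_i)(w_j'Rw_j))`, computed within each LD
#' block; features in different blocks are exactly uncorrelated. Degenerate
#' features (`w'Rw <= 1e-10`) are excluded with a message.
#'
#' @param panel a `weight_panel` (weights assumed aligned to `ld`, as the
#'   generator produces; harmonize externally-sourced panels first)
#' @param ld an `ld_reference`
#' @return object of class `feature_cor`: `$feature_id` (block-ordered) and
#'   `$blocks`, a list of lists with `feature_id` and correlation matrix `C`
#' @export
feature_correlations <- function(panel, ld) {
  feats <- panel$features
  blocks <- list()
  excluded <- 0L
  for (b in sort(unique(feats$block))) {
    rows <- which(feats$block == b)
    R <- ld$blocks[[b]]
    m <- nrow(R)
    block_snps <- ld$snps[block == b, snp]
    V <- matrix(0, m, length(rows))
    keep <- logical(length(rows))
    for (k in seq_along(rows)) {
      wtab <- panel$weights[[rows[k]]]
      idx <- match(wtab$snp, block_snps)
      V[idx, k] <- wtab$weight
    }
    Q <- crossprod(V, R %*% V)
    qf <- diag(Q)
    keep <- qf > 1e-10
    excluded <- excluded + sum(!keep)
    if (!any(keep)) next
    Q <- Q[keep, keep, drop = FALSE]
    C <- Q / tcrossprod(sqrt(diag(Q)))
    diag(C) <- 1
    blocks[[length(blocks) + 1L]] <-
      list(block = b, feature_id = feats$feature_id[rows[keep]], C = C)
  }
  if (excluded > 0L)
    message("feature_correlations: excluded ", excluded,
            " degenerate feature(s)")
  structure(list(feature_id = unlist(lapply(blocks, `[[`, "feature_id")),
                 blocks = blocks),
            class = "feature_cor")
}

#' @export
as.matrix.feature_cor <- function(x, ...) {
  n <- length(x$feature_id)
  M <- matrix(0, n, n, dimnames = list(x$feature_id, x$feature_id))
  off <- 0L
  for (bl in x$blocks) {
    k <- length(bl$feature_id)
    M[off + seq_len(k), off + seq_len(k)] <- bl$C
    off <- off + k
  }
  M
}

# coerce a plain correlation matrix into the block structure
as_feature_cor <- function(C, feature_id = NULL) {
  if (inherits(C, "feature_cor")) return(C)
  feature_id <- feature_id %||% (rownames(C) %||% sprintf("F%04d", seq_len(nrow(C))))
  structure(list(feature_id = feature_id,
                 blocks = list(list(block = 1L, feature_id = feature_id, C = C))),
            class = "feature_cor")
}

#' Transcriptome-wide significance threshold from the feature correlations
#'
#' Draws `n_draws` feature-score vectors from a zero-mean multivariate normal
#' with the block-wise feature correlation structure, records each draw's
#' minimum two-sided p across all features, and returns the `alpha_fwer`
#' quantile of that minimum-p distribution: the per-feature p threshold that
#' controls the family-wise error rate at `alpha_fwer` given the correlation
#' between features within and across weight panels.
#'
#' @param feature_cor a `feature_cor` object or a plain correlation matrix
#' @param alpha_fwer family-wise error rate (default 0.05)
#' @param n_draws Monte Carlo draws (>= 1000)
#' @param seed optional integer seed
#' @return list with `threshold` (p scale), `mc_se` (Monte Carlo SE of the
#'   threshold from order statistics), `z_equiv` (two-sided Z equivalent),
#'   `n_draws`, `n_features`
#' @export
permutation_significance_threshold <- function(feature_cor, alpha_fwer = 0.05,
                                               n_draws = 50000L, seed = NULL) {
  fc <- as_feature_cor(feature_cor)
  if (n_draws < 1000L) stop_input("n_draws must be >= 1000")
  n_feat <- length(fc$feature_id)
  if (n_feat < 2L) {
    warning("fewer than 2 features: threshold equals alpha_fwer")
    return(list(threshold = alpha_fwer, mc_se = 0,
                z_equiv = qnorm(alpha_fwer / 2, lower.tail = FALSE),
                n_draws = 0L, n_features = n_feat))
  }
  if (!is.null(seed)) set.seed(seed)
  max_abs <- rep(0, n_draws)
  for (bl in fc$blocks) {
    k <- ncol(bl$C)
    U <- chol_jitter(bl$C)
    Z <- matrix(rnorm(n_draws * k), n_draws, k) %*% U
    bm <- abs(Z[, 1])
    if (k > 1L) for (j in 2:k) bm <- pmax(bm, abs(Z[, j]))
    max_abs <- pmax(max_abs, bm)
  }
  minp <- sort(2 * pnorm(-max_abs))
  k <- max(1L, round(alpha_fwer * n_draws))
  threshold <- minp[k]
  half <- 1.96 * sqrt(n_draws * alpha_fwer * (1 - alpha_fwer))
  klo <- max(1L, floor(k - half)); khi <- min(n_draws, ceiling(k + half))
  mc_se <- (minp[khi] - minp[klo]) / (2 * 1.96)
  list(threshold = threshold, mc_se = mc_se,
       z_equiv = qnorm(threshold / 2, lower.tail = FALSE),
       n_draws = n_draws, n_features = n_feat)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR control at level `q` (wraps [stats::p.adjust()]).
#'
#' @param p_values vector of p values in `[0, 1]`
#' @param q FDR level
#' @return list with `adjusted` (BH-adjusted p values) and `discovery`
#'   (logical flags)
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L)
    return(list(adjusted = numeric(0), discovery = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_input("p values must lie in [0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, discovery = adjusted <= q)
}
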