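#' Cluster significant features into joint-analysis regions
#'
#' Single-linkage clustering of features whose boundaries, padded by
#' `window` on each side, overlap. Region bounds are the union of the padded
#' member bounds.
#'
#' @param features data.table with columns feature_id, chrom, start, stop
#'   (typically the transcriptome-wide significant rows of a TWAS scan, with
#'   p0/p1 renamed or passed as start/stop)
#' @param window padding in base pairs (default 0.5 Mb)
#' @return list with `regions` (data.table region_id, chrom, start, stop,
#'   n_features) and `membership` (data.table feature_id, region_id)
#' @export
build_regions <- function(features, window = 5e5) {
  f <- data.table::as.data.table(features)
  if (!"start" %in% names(f) && "p0" %in% names(f))
    data.table::setnames(f, c("p0", "p1"), c("start", "stop"))
  f <- f[order(chrom, start)]
  f[, `:=`(pad_lo = start - window, pad_hi = stop + window)]
  region_id <- integer(nrow(f))
  rid <- 0L
  cur_chrom <- NULL; cur_end <- -Inf
  for (i in seq_len(nrow(f))) {
    if (is.null(cur_chrom) || f$chrom[i] != cur_chrom ||
        f$pad_lo[i] > cur_end) {
      rid <- rid + 1L
      cur_chrom <- f$chrom[i]
      cur_end <- f$pad_hi[i]
    } else {
      cur_end <- max(cur_end, f$pad_hi[i])
    }
    region_id[i] <- rid
  }
  f[, region_id := region_id]
  regions <- f[, .(chrom = chrom[1], start = min(pad_lo), stop = max(pad_hi),
                   n_features = .N), by = region_id]
  list(regions = regions[], membership = f[, .(feature_id, region_id)])
}

#' Joint/conditional analysis of one region's features
#'
#' Greedy forward selection of conditionally independent associations:
#' starting from the empty model, repeatedly add the feature with the
#' smallest conditional p value (its Z residualized on already-selected
#' features through the feature correlation matrix `C`), stopping when no
#' remaining conditional p is below `threshold`. Selected features are
#' "jointly significant"; the remaining members are "marginally
#' significant" (their signal is explained by the selected set).
#'
#' @param feature_ids character vector of region member ids
#' @param z named (or aligned) TWAS Z vector for the members
#' @param C feature correlation submatrix for the members
#' @param threshold p-value retention threshold (the transcriptome-wide
#'   threshold)
#' @param ridge diagonal ridge used if `C` submatrices are singular
#' @return list with `jointly`, `marginally` (feature id vectors) and
#'   `trace` (data.table feature_id, step, cond_z, cond_p for the selected)
#' @export
joint_conditional_analysis <- function(feature_ids, z, C, threshold,
                                       ridge = 1e-6) {
  k <- length(feature_ids)
  stopifnot(length(z) == k, nrow(C) == k)
  selected <- integer(0)
  trace <- list()
  repeat {
    cand <- setdiff(seq_len(k), selected)
    if (length(cand) == 0L) break
    cz <- vapply(cand, function(j) conditional_z(j, selected, z, C, ridge),
                 numeric(1))
    cp <- z_to_p(cz)
    best <- which.min(cp)
    if (cp[best] >= threshold) break
    selected <- c(selected, cand[best])
    trace[[length(trace) + 1L]] <- data.table::data.table(
      feature_id = feature_ids[cand[best]], step = length(selected),
      cond_z = cz[best], cond_p = cp[best])
  }
  list(jointly = feature_ids[selected],
       marginally = setdiff(feature_ids, feature_ids[selected]),
       trace = data.table::rbindlist(trace))
}

#' Z of feature j conditioned on a selected feature set through C
#' @param j index of the feature to condition
#' @param selected indices of the conditioning features
#' @param z TWAS Z vector
#' @param C feature correlation matrix
#' @param ridge diagonal ridge used if `C` is singular
#' @return the conditional Z score
#' @export
conditional_z <- function(j, selected, z, C, ridge = 1e-6) {
  if (length(selected) == 0L) return(z[j])
  Css <- C[selected, selected, drop = FALSE]
  cjs <- C[j, selected]
  a <- solve_ridge(Css, cbind(z[selected], cjs), ridge)
  denom2 <- 1 - drop(cjs %*% a[, 2])
  if (denom2 <= 1e-8) return(0)
  (z[j] - drop(cjs %*% a[, 1])) / sqrt(denom2)
}

#' Correlation between each SNP and a feature's predicted expression
#'
#' `rho_j = (Rw)_j / sqrt(w'Rw)` for every SNP of the feature's LD block.
#'
#' @param w aligned weight vector (length = number of weight SNPs)
#' @param R block LD matrix
#' @param idx positions of the weight SNPs within the block
#' @return numeric vector, one entry per block SNP
#' @export
snp_feature_correlation <- function(w, R, idx) {
  v <- drop(R[, idx, drop = FALSE] %*% w)
  qf <- drop(crossprod(w, R[idx, idx, drop = FALSE] %*% w))
  v / sqrt(qf)
}

#' Condition GWAS SNP statistics on predicted expression
#'
#' For each SNP, `z_cond = (z - r'C^{-1}z_feat) / sqrt(1 - r'C^{-1}r)` where
#' `r` holds the SNP's correlations with the conditioning features'
#' predicted expression, `C` is the feature correlation matrix and `z_feat`
#' the features' TWAS Z scores. The fraction of the SNP association
#' explained is `1 - chi2_cond / chi2_uncond`. A SNP collinear with the
#' feature set (`1 - r'C^{-1}r <= 1e-8`) is reported as fully explained.
#'
#' @param z_snp numeric vector of unconditioned SNP Z scores
#' @param r_sf matrix (n_snp x n_features) of SNP-feature correlations (a
#'   vector is accepted for a single feature)
#' @param C feature correlation matrix of the conditioning features
#' @param z_feat TWAS Z scores of the conditioning features
#' @param ridge diagonal ridge used if `C` is singular
#' @return data.table with z_uncond, z_cond, variance_explained
#' @export
condition_gwas_on_features <- function(z_snp, r_sf, C, z_feat, ridge = 1e-6) {
  r_sf <- matrix(r_sf, nrow = length(z_snp))
  C <- matrix(C, nrow = length(z_feat))
  a <- solve_ridge(C, z_feat, ridge)
  B <- t(solve_ridge(C, t(r_sf), ridge))   # n_snp x k, rows r'C^{-1}
  num <- z_snp - drop(r_sf %*% a)
  denom2 <- 1 - rowSums(B * r_sf)
  collinear <- denom2 <= 1e-8
  z_cond <- ifelse(collinear, 0, num / sqrt(pmax(denom2, 1e-12)))
  ve <- ifelse(collinear, 1,
               ifelse(z_snp != 0, 1 - z_cond^2 / z_snp^2, NA_real_))
  data.table::data.table(z_uncond = z_snp, z_cond = z_cond,
                         variance_explained = ve)
}

#' Omnibus test pooling a gene's evidence across weight panels
#'
#' Multiple-degrees-of-freedom chi-square test on the panel TWAS Z vector,
#' whitened by the eigendecomposition of the panel correlation matrix;
#' components with eigenvalue below `tol * max(eigenvalue)` are discarded so
#' perfectly redundant panels do not inflate the degrees of freedom.
#'
#' @param z TWAS Z scores of one gene across panels
#' @param C correlation matrix of those features' predicted expression
#' @param tol relative eigenvalue cutoff
#' @return list with `stat`, `df`, `p`
#' @export
omnibus_test <- function(z, C, tol = 1e-4) {
  C <- matrix(C, nrow = length(z))
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  proj <- drop(crossprod(e$vectors[, keep, drop = FALSE], z))
  stat <- sum(proj^2 / e$values[keep])
  df <- sum(keep)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' SNP-wise mean gene-based test (functionally agnostic)
#'
#' Mean GWAS chi-square over the SNPs within `window_kb` of the gene, with
#' the null distribution of the quadratic form `sum lambda_i chi2_1 / m`
#' (lambda = eigenvalues of the window's LD matrix) approximated by a
#' moment-matched (Satterthwaite) scaled chi-square.
#'
#' @param gene list or one-row data.frame with chrom, start, stop
#' @param sumstats GWAS summary statistics with snp and z columns
#' @param ld an `ld_reference`
#' @param window_kb window each side of the gene, in kb (default 10)
#' @return `NULL` if no SNP falls in the window, else a list with `stat`
#'   (mean chi-square), `n_snps`, `p`
#' @export
snpwise_mean_region_test <- function(gene, sumstats, ld, window_kb = 10) {
  w_bp <- window_kb * 1000
  sel <- ld$snps[chrom == gene$chrom & pos >= gene$start - w_bp &
                 pos <= gene$stop + w_bp]
  sel[, z := sumstats$z[match(snp, sumstats$snp)]]
  sel <- sel[is.finite(z)]
  if (nrow(sel) == 0L) {
    message("snpwise_mean_region_test: no SNPs in window, gene skipped")
    return(NULL)
  }
  m <- nrow(sel)
  lambda <- unlist(lapply(split(sel, sel$block), function(s) {
    b <- s$block[1]
    block_snps <- ld$snps[block == b, snp]
    idx <- match(s$snp, block_snps)
    eigen(ld$blocks[[b]][idx, idx, drop = FALSE], symmetric = TRUE,
          only.values = TRUE)$values
  }), use.names = FALSE)
  Q <- sum(sel$z^2)
  s <- sum(lambda^2) / sum(lambda)
  nu <- sum(lambda)^2 / sum(lambda^2)
  list(stat = Q / m, n_snps = m,
       p = pchisq(Q / s, nu, lower.tail = FALSE))
}

#' Regional joint-analysis report
#'
#' Merges the per-stage outputs into one row per region of transcriptome-wide
#' significant features: region location, the minimum TWAS p, the minimum
#' GWAS SNP p within 500 kb of the jointly significant genes, the minimum
#' SNP-wise-mean gene p, the fraction of the top GWAS SNP association
#' explained by the region's most significant feature, and the jointly /
#' marginally significant gene lists.
#'
#' @param twas_results output of [twas_scan()] with `tw_sig` flags
#' @param sumstats GWAS summary statistics
#' @param panel the `weight_panel`
#' @param ld the `ld_reference`
#' @param fc `feature_cor` from [feature_correlations()]
#' @param threshold transcriptome-wide significance threshold (p scale)
#' @param window joint-model clustering window in bp (default 0.5 Mb)
#' @param gwas_window window around jointly significant genes for the top
#'   GWAS SNP, in bp (default 500 kb)
#' @return data.table with one row per region: location, minp_twas,
#'   minp_gwas, minp_regiontest, var_explained_pct, jointly_sig,
#'   marginally_sig
#' @export
region_report <- function(twas_results, sumstats, panel, ld, fc, threshold,
                          window = 5e5, gwas_window = 5e5) {
  sig <- twas_results[tw_sig == TRUE]
  if (nrow(sig) == 0L) return(data.table::data.table())
  reg <- build_regions(sig[, .(feature_id, chrom, start = p0, stop = p1)],
                       window = window)
  Cfull <- as.matrix(fc)
  out <- vector("list", nrow(reg$regions))
  for (ri in seq_len(nrow(reg$regions))) {
    ids <- reg$membership[region_id == ri, feature_id]
    rows <- sig[feature_id %in% ids]
    ord <- match(rows$feature_id, colnames(Cfull))
    C <- Cfull[ord, ord, drop = FALSE]
    jc <- joint_conditional_analysis(rows$feature_id, rows$twas_z, C,
                                     threshold)
    # top GWAS SNP near the jointly significant genes
    jrows <- rows[feature_id %in% jc$jointly]
    ss <- sumstats[match(ld$snps$snp, snp)]
    near <- rep(FALSE, nrow(ld$snps))
    for (g in seq_len(nrow(jrows)))
      near <- near | (ld$snps$chrom == jrows$chrom[g] &
                      ld$snps$pos >= jrows$p0[g] - gwas_window &
                      ld$snps$pos <= jrows$p1[g] + gwas_window)
    near <- near & is.finite(ss$z)
    ve_pct <- NA_real_
    minp_gwas <- NA_real_
    if (any(near)) {
      zg <- ss$z[near]
      top <- which.max(abs(zg))
      minp_gwas <- z_to_p(zg[top])
      top_global <- which(near)[top]
      # explain the top SNP with the region's most significant feature
      bestf <- rows$feature_id[which.min(rows$twas_p)]
      bi <- match(bestf, panel$features$feature_id)
      h <- harmonize_alleles(sumstats, panel$weights[[bi]], ld)
      if (!is.null(h) && ld$snps$block[top_global] == h$block) {
        rho <- snp_feature_correlation(h$w, ld$blocks[[h$block]], h$idx)
        pos_in_block <- match(ld$snps$snp[top_global],
                              ld$snps[block == h$block, snp])
        zt <- rows[feature_id == bestf, twas_z]
        cond <- condition_gwas_on_features(zg[top], rho[pos_in_block],
                                           matrix(1), zt)
        ve_pct <- 100 * cond$variance_explained
      } else ve_pct <- 0
    }
    # SNP-wise mean test over member genes
    mp_region <- suppressMessages(min(vapply(seq_len(nrow(rows)), function(g) {
      r <- snpwise_mean_region_test(
        list(chrom = rows$chrom[g], start = rows$p0[g], stop = rows$p1[g]),
        sumstats, ld)
      if (is.null(r)) NA_real_ else r$p
    }, numeric(1)), na.rm = TRUE))
    out[[ri]] <- data.table::data.table(
      location = sprintf("chr%s:%d-%d", reg$regions$chrom[ri],
                         as.integer(reg$regions$start[ri]),
                         as.integer(reg$regions$stop[ri])),
      minp_twas = min(rows$twas_p),
      minp_gwas = minp_gwas,
      minp_regiontest = mp_region,
      var_explained_pct = ve_pct,
      jointly_sig = paste(jc$jointly, collapse = ","),
      marginally_sig = paste(jc$marginally, collapse = ","))
  }
  data.table::rbindlist(out)
}
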