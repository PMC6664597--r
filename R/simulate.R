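#' Simulation configuration for a synthetic TWAS study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe a desk-scale study with the statistical structure of a
#' case-control GWAS integrated with one expression SNP-weight panel:
#' block-diagonal AR(1) LD, sparse cis weight vectors with a fixed
#' cis-heritability, gene-mediated plus direct ("background") SNP effects,
#' and gene sets of which a subset may be enriched.
#'
#' Default rationale: `n_gwas = 46350` is a modern psychiatric-GWAS effective
#' sample size (18,381 cases + 27,969 controls); `cis_h2 = 0.2` is a typical
#' cis-heritability for an expressed gene; `ar_rho = 0.8` gives realistic
#' short-range LD decay; `gene_effect_sd` and `direct_effect_sd` default so
#' that mediated heritability is roughly 13% of a total observed-scale
#' heritability of 0.12 at the default SNP and feature counts.
#'
#' @param n_blocks number of independent LD blocks
#' @param snps_per_block SNPs per block
#' @param ar_rho AR(1) within-block LD correlation, in `[0, 1)`
#' @param n_features number of expression features (gene x panel units)
#' @param weight_sparsity fraction of a block's SNPs given nonzero weight
#' @param cis_h2 predicted-expression variance target `w'Rw`, in `[0, 1]`
#' @param n_gwas GWAS effective sample size
#' @param gene_effect_sd SD of the gene-mediated effect alpha per feature
#' @param direct_effect_sd SD of direct (non-mediated) per-SNP effects
#' @param n_sets number of gene sets
#' @param set_size genes per set
#' @param enriched_effect additive inflation of alpha^2 for enriched-set genes
#' @param seed integer seed; fully determines all generator output
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_blocks = 40L, snps_per_block = 100L, ar_rho = 0.8,
                       n_features = 400L, weight_sparsity = 0.05,
                       cis_h2 = 0.2, n_gwas = 46350L,
                       gene_effect_sd = sqrt(0.0156 / 400),
                       direct_effect_sd = sqrt(0.1044 / 4000),
                       n_sets = 100L, set_size = 20L,
                       enriched_effect = 0, seed = 1L) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              ar_rho = ar_rho, n_features = as.integer(n_features),
              weight_sparsity = weight_sparsity, cis_h2 = cis_h2,
              n_gwas = n_gwas, gene_effect_sd = gene_effect_sd,
              direct_effect_sd = direct_effect_sd,
              n_sets = as.integer(n_sets), set_size = as.integer(set_size),
              enriched_effect = enriched_effect, seed = as.integer(seed))
  with(cfg, {
    if (n_blocks < 1L || snps_per_block < 1L || n_features < 1L ||
        n_sets < 0L || set_size < 1L)
      stop_input("all counts must be positive")
    if (ar_rho < 0 || ar_rho >= 1) stop_input("ar_rho must be in [0, 1)")
    if (cis_h2 < 0 || cis_h2 > 1) stop_input("cis_h2 must be in [0, 1]")
    if (n_gwas <= 0) stop_input("n_gwas must be positive")
  })
  structure(cfg, class = "sim_config")
}

# non-strand-ambiguous allele pairs (A/T and C/G excluded by construction so
# nothing the generator emits is dropped at harmonization)
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate a block-diagonal AR(1) LD reference
#'
#' Every block has correlation `R[i, j] = ar_rho^|i - j|`; blocks are exactly
#' independent. SNPs get 1-based positions with 1 kb spacing within a block
#' and a 2 Mb gap between blocks, and non-strand-ambiguous alleles.
#'
#' @inheritParams sim_config
#' @param seed optional integer seed (`NULL` uses the current RNG state)
#' @param chrom chromosome label for all SNPs
#' @return an object of class `ld_reference`: `$snps` (data.table with
#'   columns snp, chrom, pos, a1, a2, block) and `$blocks` (list of
#'   correlation matrices, one per block)
#' @export
simulate_ld_blocks <- function(n_blocks, snps_per_block, ar_rho, seed = NULL,
                               chrom = 1L) {
  if (n_blocks < 1L || snps_per_block < 1L)
    stop_input("n_blocks and snps_per_block must be positive")
  if (ar_rho < 0 || ar_rho >= 1) stop_input("ar_rho must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(snps_per_block)
  R <- ar_rho^abs(outer(seq_len(m), seq_len(m), `-`))
  n_snp <- n_blocks * m
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), n_snp, replace = TRUE), ,
                        drop = FALSE]
  block_start <- (seq_len(n_blocks) - 1L) * (m * 1000L + 2e6)
  snps <- data.table::data.table(
    snp = sprintf("rs%07d", seq_len(n_snp)),
    chrom = chrom,
    pos = as.integer(rep(block_start, each = m) + (seq_len(m) - 1L) * 1000L + 1L),
    a1 = pair[, 1], a2 = pair[, 2],
    block = rep(seq_len(n_blocks), each = m))
  structure(list(snps = snps, blocks = rep(list(R), n_blocks)),
            class = "ld_reference")
}

# upper-triangular Cholesky factors, one per block, cached on the object
ld_chols <- function(ld) {
  ch <- attr(ld, "chol")
  if (is.null(ch)) lapply(ld$blocks, chol) else ch
}

#' Simulate a sparse cis SNP-weight panel
#'
#' Each feature is assigned to one LD block; a sparse subset of the block's
#' SNPs receives Gaussian weights, rescaled so the predicted-expression
#' variance `w'Rw` equals `cis_h2` exactly. Gene boundaries are the span of
#' the feature's weight SNPs.
#'
#' @param ld an `ld_reference`
#' @inheritParams sim_config
#' @param panel_id label written to the manifest
#' @param gene_ids optional gene ids (one per feature) so that several panels
#'   can share genes; default assigns one gene per feature
#' @param seed optional integer seed
#' @return an object of class `weight_panel`: `$features` manifest
#'   (feature_id, gene_id, panel_id, chrom, start, stop, block, cis_h2,
#'   n_snps) and `$weights`, a named list of data.tables
#'   (snp, a1, a2, weight)
#' @export
simulate_weight_panel <- function(ld, n_features, weight_sparsity = 0.05,
                                  cis_h2 = 0.2, seed = NULL,
                                  panel_id = "PANEL1", gene_ids = NULL) {
  if (n_features < 1L) stop_input("n_features must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- length(ld$blocks)
  m <- nrow(ld$blocks[[1]])
  n_nz <- round(weight_sparsity * m)
  if (n_nz < 1L)
    stop_input("weight_sparsity selects zero SNPs per feature")
  block_of <- sample(rep_len(seq_len(n_blocks), n_features))
  gene_ids <- gene_ids %||% sprintf("G%05d", seq_len(n_features))
  feature_id <- paste(panel_id, gene_ids, sep = ".")

  weights <- vector("list", n_features)
  start <- stop <- integer(n_features)
  for (i in seq_len(n_features)) {
    b <- block_of[i]
    R <- ld$blocks[[b]]
    idx <- sort(sample.int(m, n_nz))
    w <- rnorm(n_nz)
    qf <- drop(crossprod(w, R[idx, idx, drop = FALSE] %*% w))
    w <- w * sqrt(cis_h2 / qf)
    snp_rows <- ld$snps[block == b][idx]
    weights[[i]] <- data.table::data.table(
      snp = snp_rows$snp, a1 = snp_rows$a1, a2 = snp_rows$a2, weight = w)
    start[i] <- min(snp_rows$pos); stop[i] <- max(snp_rows$pos)
  }
  names(weights) <- feature_id
  features <- data.table::data.table(
    feature_id = feature_id, gene_id = gene_ids, panel_id = panel_id,
    chrom = ld$snps$chrom[1], start = start, stop = stop,
    block = block_of, cis_h2 = cis_h2, n_snps = n_nz)
  structure(list(features = features, weights = weights),
            class = "weight_panel")
}

#' Simulate GWAS summary statistics with gene-mediated effects
#'
#' Marginal Z scores are drawn block-wise from the standard summary-statistic
#' model `z = sqrt(N) R beta + e`, `e ~ MVN(0, R)`, where the joint effect
#' vector `beta` sums iid direct SNP effects and gene-mediated effects
#' `alpha_f * w_f / sqrt(w_f' R w_f)` (weights scaled to unit
#' predicted-expression variance, so `alpha_f` is the standardized effect of
#' the feature's predicted expression and `E[Z_TWAS] = sqrt(N) alpha_f`).
#'
#' @param ld an `ld_reference`
#' @param panel a `weight_panel`
#' @param alpha numeric vector of gene-mediated effects, one per panel feature
#' @param direct_effect_sd SD of direct per-SNP effects
#' @param n_gwas GWAS effective sample size
#' @param seed optional integer seed
#' @return data.table with columns snp, chrom, pos, a1, a2, z, n
#' @export
simulate_gwas_sumstats <- function(ld, panel, alpha, direct_effect_sd = 0,
                                   n_gwas, seed = NULL) {
  if (length(alpha) != nrow(panel$features))
    stop_input("alpha must have one entry per panel feature")
  if (n_gwas <= 0) stop_input("n_gwas must be positive")
  if (!is.null(seed)) set.seed(seed)
  chols <- ld_chols(ld)
  snps <- ld$snps
  z <- numeric(nrow(snps))
  feat_block <- panel$features$block
  for (b in seq_along(ld$blocks)) {
    R <- ld$blocks[[b]]
    m <- nrow(R)
    rows <- which(snps$block == b)
    beta <- rnorm(m, 0, direct_effect_sd)
    for (i in which(feat_block == b)) {
      wtab <- panel$weights[[i]]
      idx <- match(wtab$snp, snps$snp[rows])
      h2 <- panel$features$cis_h2[i]
      beta[idx] <- beta[idx] + alpha[i] * wtab$weight / sqrt(h2)
    }
    z[rows] <- sqrt(n_gwas) * drop(R %*% beta) +
      drop(crossprod(chols[[b]], rnorm(m)))
  }
  data.table::data.table(snp = snps$snp, chrom = snps$chrom, pos = snps$pos,
                         a1 = snps$a1, a2 = snps$a2, z = z, n = n_gwas)
}

#' Simulate marginal Z scores for one region
#'
#' Single-block convenience version of the summary-statistic model, used for
#' colocalization experiments: `z = sqrt(n) R beta + e`, `e ~ MVN(0, R)`.
#'
#' @param R SNP correlation matrix of the region
#' @param beta joint standardized effect vector (length `nrow(R)`)
#' @param n sample size
#' @param chol_R optional precomputed `chol(R)`
#' @return numeric Z vector
#' @export
simulate_region_z <- function(R, beta, n, chol_R = NULL) {
  U <- chol_R %||% chol(R)
  sqrt(n) * drop(R %*% beta) + drop(crossprod(U, rnorm(nrow(R))))
}

#' Simulate gene sets, property scores and the ground-truth table
#'
#' Gene sets are sampled without replacement; genes in enriched sets have
#' their mediated-effect variance inflated by `enriched_effect`, and the
#' per-feature alpha values are drawn accordingly (propagated from gene to
#' all its features). Property scores (one column per developmental stage)
#' are drawn with target correlation `prop_cor` to alpha^2.
#'
#' @param panel a `weight_panel`
#' @inheritParams sim_config
#' @param n_enriched number of enriched sets (default: 10% of `n_sets` when
#'   `enriched_effect > 0`, else 0)
#' @param prop_cor target correlation between each stage score and alpha^2
#' @param n_stages number of property-score columns
#' @param seed optional integer seed
#' @return list with `$sets` (named list of gene-id vectors), `$properties`
#'   (data.table gene + STAGE_1..), `$alpha` (per-feature effect vector) and
#'   `$truth` (list of `features` and `sets` ground-truth data.tables)
#' @export
simulate_gene_sets_and_properties <- function(panel, n_sets, set_size,
                                              enriched_effect = 0,
                                              gene_effect_sd = 0.01,
                                              n_enriched = NULL,
                                              prop_cor = 0, n_stages = 19L,
                                              seed = NULL) {
  genes <- unique(panel$features$gene_id)
  G <- length(genes)
  if (set_size >= G)
    stop_input("set_size must be smaller than the number of genes")
  if (!is.null(seed)) set.seed(seed)
  n_enriched <- n_enriched %||%
    (if (enriched_effect > 0) max(1L, round(0.1 * n_sets)) else 0L)

  sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  enriched <- rep(FALSE, n_sets)
  if (n_enriched > 0) enriched[sample.int(n_sets, n_enriched)] <- TRUE

  in_enriched <- genes %in% unlist(sets[enriched], use.names = FALSE)
  alpha_var <- gene_effect_sd^2 + enriched_effect * in_enriched
  alpha_gene <- rnorm(G, 0, sqrt(alpha_var))
  alpha <- alpha_gene[match(panel$features$gene_id, genes)]

  a2s <- as.numeric(scale(alpha_gene^2))
  scores <- sapply(seq_len(n_stages), function(s)
    prop_cor * a2s + sqrt(1 - prop_cor^2) * rnorm(G))
  properties <- data.table::data.table(gene = genes)
  properties[, sprintf("STAGE_%d", seq_len(n_stages)) :=
               as.data.table(scores)]

  truth <- list(
    features = data.table::data.table(
      feature_id = panel$features$feature_id,
      gene_id = panel$features$gene_id,
      alpha = alpha,
      alpha_var = alpha_var[match(panel$features$gene_id, genes)]),
    sets = data.table::data.table(
      set_id = names(sets), enriched = enriched,
      effect = ifelse(enriched, enriched_effect, 0)))
  list(sets = sets, properties = properties, alpha = alpha, truth = truth)
}

#' Run the full generator from a configuration
#'
#' Convenience wrapper producing every input the inference chain consumes,
#' with the ground truth attached.
#'
#' @param cfg a `sim_config`
#' @return list with `ld`, `panel`, `sets`, `properties`, `alpha`, `truth`,
#'   `sumstats`
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ld <- simulate_ld_blocks(cfg$n_blocks, cfg$snps_per_block, cfg$ar_rho)
  panel <- simulate_weight_panel(ld, cfg$n_features, cfg$weight_sparsity,
                                 cfg$cis_h2)
  gs <- simulate_gene_sets_and_properties(
    panel, cfg$n_sets, cfg$set_size, cfg$enriched_effect, cfg$gene_effect_sd)
  sumstats <- simulate_gwas_sumstats(ld, panel, gs$alpha,
                                     cfg$direct_effect_sd, cfg$n_gwas)
  list(ld = ld, panel = panel, sets = gs$sets, properties = gs$properties,
       alpha = gs$alpha, truth = gs$truth, sumstats = sumstats)
}
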