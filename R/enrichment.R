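#' Positive-oriented association Z from two-sided p values
#'
#' `Z_assoc = qnorm(1 - p)`: monotone decreasing in p, zero at p = 0.5,
#' standard normal under the null (where two-sided p values are uniform).
#' Using the magnitude-based transform rather than the signed TWAS Z keeps a
#' competitive enrichment test from cancelling opposite-direction effects.
#'
#' @param two_sided_p vector of two-sided p values in `(0, 1]`
#' @return numeric vector of association Z scores
#' @export
association_z_transform <- function(two_sided_p) {
  p <- two_sided_p
  if (any(p < 0 | p > 1)) stop_input("p values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p = 0 clamped to the smallest representable double")
    p[p == 0] <- .Machine$double.xmin
  }
  # keep p = 1 finite: clamp to the largest double below 1
  p <- pmin(p, 1 - .Machine$double.eps / 2)
  qnorm(p, lower.tail = FALSE)
}

#' Feature-relatedness matrix for the enrichment mixed model
#'
#' `K` is assembled block-wise from the squared predicted-expression
#' correlations (the sign of the correlation is irrelevant to how strongly
#' two features' association statistics covary). Each block is forced
#' positive semidefinite by clipping negative eigenvalues to zero and
#' renormalized to unit diagonal; the block eigendecompositions are stored
#' for the mixed-model fit.
#'
#' @param fc a `feature_cor` from [feature_correlations()] (or a plain
#'   correlation matrix)
#' @return object of class `feature_relatedness` with `$feature_id`,
#'   `$blocks` (idx, U, lambda per block) and `$K` (dense matrix)
#' @export
build_feature_relatedness <- function(fc) {
  fc <- as_feature_cor(fc)
  n <- length(fc$feature_id)
  K <- matrix(0, n, n, dimnames = list(fc$feature_id, fc$feature_id))
  blocks <- vector("list", length(fc$blocks))
  off <- 0L
  for (bi in seq_along(fc$blocks)) {
    Cb <- fc$blocks[[bi]]$C
    k <- nrow(Cb)
    Kb <- Cb^2
    e <- eigen(Kb, symmetric = TRUE)
    if (any(e$values < 0)) {
      lam <- pmax(e$values, 0)
      Kb <- e$vectors %*% (lam * t(e$vectors))
      d <- pmax(diag(Kb), 1e-12)
      Kb <- Kb / tcrossprod(sqrt(d))
      e <- eigen(Kb, symmetric = TRUE)
    }
    idx <- off + seq_len(k)
    K[idx, idx] <- Kb
    blocks[[bi]] <- list(idx = idx, U = e$vectors,
                         lambda = pmax(e$values, 0))
    off <- off + k
  }
  structure(list(feature_id = fc$feature_id, blocks = blocks, K = K),
            class = "feature_relatedness")
}

# rotate a vector/matrix into the eigenbasis of K, block by block
rel_rotate <- function(rel, x) {
  x <- as.matrix(x)
  out <- x
  for (bl in rel$blocks)
    out[bl$idx, ] <- crossprod(bl$U, x[bl$idx, , drop = FALSE])
  out
}

#' Eigenvalues of a feature-relatedness matrix in feature order
#' @param rel a `feature_relatedness`
#' @return numeric vector of (block) eigenvalues
#' @export
rel_lambda <- function(rel) {
  lam <- numeric(length(rel$feature_id))
  for (bl in rel$blocks) lam[bl$idx] <- bl$lambda
  lam
}

# restrict a relatedness object to a subset of features
subset_relatedness <- function(rel, keep) {
  keep <- which(keep)
  Ksub <- rel$K[keep, keep, drop = FALSE]
  n <- length(keep)
  e <- eigen(Ksub, symmetric = TRUE)
  structure(list(feature_id = rel$feature_id[keep],
                 blocks = list(list(idx = seq_len(n), U = e$vectors,
                                    lambda = pmax(e$values, 0))),
                 K = Ksub),
            class = "feature_relatedness")
}

# REML fit of y = X b + g + e, cov(g) = sg2 K, cov(e) = se2 I, on the
# eigenbasis of K: V = se2 (I + delta Lambda), delta = sg2/se2 profiled by
# 1-D bounded search over log(delta).
lmm_reml <- function(y, X, rel) {
  n <- length(y)
  p <- ncol(X)
  ystar <- drop(rel_rotate(rel, y))
  Xstar <- rel_rotate(rel, X)
  lam <- rel_lambda(rel)

  fit_at <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (1 + delta * lam)
    XtWX <- crossprod(Xstar, Xstar * w)
    XtWy <- crossprod(Xstar, ystar * w)
    b <- solve(XtWX, XtWy)
    r <- ystar - drop(Xstar %*% b)
    rss <- sum(w * r^2)
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(sigma2) + sum(log1p(delta * lam)) +
                  determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), b = drop(b), sigma2 = sigma2, XtWX = XtWX,
         delta = delta)
  }

  opt <- tryCatch({
    o <- optimize(function(ld) fit_at(ld)$ll, interval = c(-12, 10),
                  maximum = TRUE)
    best <- fit_at(o$maximum)
    null_fit <- fit_at(-50)  # delta ~ 0 (OLS) boundary
    if (null_fit$ll >= best$ll) null_fit else best
  }, error = function(e) {
    warning("REML did not converge; falling back to sigma2_g = 0 (OLS)")
    fit_at(-50)
  })

  se <- sqrt(opt$sigma2 * diag(solve(opt$XtWX)))
  list(beta = opt$b, se = se, t = opt$b / se, df = n - p,
       delta = opt$delta, sigma2_e = opt$sigma2,
       sigma2_g = opt$sigma2 * opt$delta)
}

#' Competitive gene-set enrichment test
#'
#' Linear mixed model regression of the association Z score on set
#' membership, `z = b0 + beta_s s (+ covariates) + g + e` with
#' `cov(g) = sigma2_g K` absorbing the correlation between features due to
#' LD. Variance components by REML on the eigenbasis of `K`; one-sided Wald
#' p for enrichment (`beta_s > 0`) with a t reference on `n - p` degrees of
#' freedom. With `K = identity` the fit reduces exactly to OLS.
#'
#' @param z_assoc association Z vector, one per feature
#'   (see [association_z_transform()])
#' @param membership logical or 0/1 indicator, one per feature
#' @param rel a `feature_relatedness`
#' @param covariates optional numeric matrix of fixed-effect covariates
#' @param set_id label carried into the result
#' @return one-row data.table: set_id, n_members, beta, se, p_one_sided
#' @export
competitive_set_test <- function(z_assoc, membership, rel, covariates = NULL,
                                 set_id = "set") {
  s <- as.numeric(membership)
  n <- length(z_assoc)
  if (sum(s) < 1 || sum(s) >= n)
    stop_input("degenerate set: membership must be neither empty nor universal")
  X <- cbind(`(Intercept)` = 1, set = s)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- lmm_reml(z_assoc, X, rel)
  data.table::data.table(
    set_id = set_id, n_members = as.integer(sum(s)),
    beta = fit$beta[2], se = fit$se[2],
    p_one_sided = pt(fit$t[2], fit$df, lower.tail = FALSE))
}

#' Gene-set enrichment over a GMT-style collection
#'
#' Runs [competitive_set_test()] for every set, propagating gene-level
#' membership to all features of a gene, and attaches FDR-adjusted p values
#' across sets.
#'
#' @param z_assoc association Z per feature
#' @param gene_ids gene id per feature (same order)
#' @param sets named list of gene-id vectors
#' @param rel a `feature_relatedness`
#' @param covariates optional fixed-effect covariates
#' @return data.table: set_id, n_members, beta, se, p_one_sided, fdr_p
#' @export
enrichment_gene_sets <- function(z_assoc, gene_ids, sets, rel,
                                 covariates = NULL) {
  res <- vector("list", length(sets))
  skipped <- 0L
  for (i in seq_along(sets)) {
    s <- gene_ids %in% sets[[i]]
    if (sum(s) < 1 || sum(s) >= length(s)) { skipped <- skipped + 1L; next }
    res[[i]] <- competitive_set_test(z_assoc, s, rel, covariates,
                                     set_id = names(sets)[i])
  }
  if (skipped > 0L)
    message("enrichment_gene_sets: skipped ", skipped, " degenerate set(s)")
  out <- data.table::rbindlist(res)
  out[, fdr_p := p.adjust(p_one_sided, method = "BH")]
  out[]
}

#' Gene-property (continuous annotation) enrichment test
#'
#' One mixed-model fit per property column (e.g. preferential-expression
#' score at each developmental stage), with the column centered and scaled
#' as the continuous predictor. Two-sided p values with a Bonferroni flag at
#' `alpha / n_stages`.
#'
#' @param z_assoc association Z per feature
#' @param scores numeric matrix of property scores, one row per feature, one
#'   column per stage
#' @param rel a `feature_relatedness`
#' @param alpha family-wise level for the Bonferroni flag (default 0.05)
#' @return data.table: stage, beta, se, p_two_sided, bonf_sig
#' @export
property_gradient_test <- function(z_assoc, scores, rel, alpha = 0.05) {
  scores <- as.matrix(scores)
  stages <- colnames(scores) %||% sprintf("STAGE_%d", seq_len(ncol(scores)))
  res <- vector("list", ncol(scores))
  for (j in seq_len(ncol(scores))) {
    x <- scores[, j]
    if (!all(is.finite(x))) stop_input("property scores must be finite")
    if (sd(x) == 0) {
      message("property_gradient_test: constant score column '", stages[j],
              "' skipped")
      next
    }
    X <- cbind(`(Intercept)` = 1, score = as.numeric(scale(x)))
    fit <- lmm_reml(z_assoc, X, rel)
    res[[j]] <- data.table::data.table(
      stage = stages[j], beta = fit$beta[2], se = fit$se[2],
      p_two_sided = 2 * pt(-abs(fit$t[2]), fit$df))
  }
  out <- data.table::rbindlist(res)
  out[, bonf_sig := p_two_sided < alpha / ncol(scores)]
  out[]
}

#' SNP-weight-set (panel) enrichment
#'
#' For each panel, a competitive test of that panel's features against all
#' other analyzed features; optionally restricted to a subset of panels
#' (e.g. the basal ganglia regions only), in which case features and the
#' relatedness matrix are re-subset first.
#'
#' @param z_assoc association Z per feature
#' @param panel_labels panel id per feature (same order)
#' @param rel a `feature_relatedness`
#' @param restrict_to optional character vector of panel ids to restrict the
#'   comparison to (must leave at least two panels)
#' @return data.table: set_id (panel), n_members, beta, se, p_one_sided,
#'   fdr_p
#' @export
weight_set_enrichment <- function(z_assoc, panel_labels, rel,
                                  restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    keep <- panel_labels %in% restrict_to
    if (length(unique(panel_labels[keep])) < 2L)
      stop_input("restriction leaves fewer than two panels")
    z_assoc <- z_assoc[keep]
    panel_labels <- panel_labels[keep]
    rel <- subset_relatedness(rel, keep)
  }
  panels <- unique(panel_labels)
  if (length(panels) < 2L) stop_input("at least two panels are required")
  res <- data.table::rbindlist(lapply(panels, function(p)
    competitive_set_test(z_assoc, panel_labels == p, rel, set_id = p)))
  res[, fdr_p := p.adjust(p_one_sided, method = "BH")]
  res[]
}
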