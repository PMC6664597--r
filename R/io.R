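#' Read GWAS summary statistics (sumstats dialect)
#'
#' Tab-separated with header columns SNP, A1, A2, Z, N (extra columns such
#' as CHR/BP are carried through). Duplicate SNP ids are a format error;
#' rows with non-finite Z are dropped and counted.
#'
#' @param path file path
#' @return data.table with columns snp, a1, a2, z, n (plus chrom/pos when
#'   CHR/BP are present); attribute `n_dropped` counts removed rows
#' @export
read_sumstats <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("SNP", "A1", "A2", "Z", "N")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L)
    stop_input("sumstats format error: missing column ", miss[1])
  if (anyDuplicated(dt$SNP))
    stop_input("sumstats format error: duplicated SNP id")
  dt[, Z := suppressWarnings(as.numeric(Z))]
  bad <- !is.finite(dt$Z)
  if (any(bad)) {
    message("read_sumstats: dropped ", sum(bad), " row(s) with non-finite Z")
    dt <- dt[!bad]
  }
  out <- data.table::data.table(snp = dt$SNP, a1 = dt$A1, a2 = dt$A2,
                                z = dt$Z, n = dt$N)
  if (all(c("CHR", "BP") %in% names(dt)))
    out[, `:=`(chrom = dt$CHR, pos = dt$BP)]
  data.table::setattr(out, "n_dropped", sum(bad))
  out
}

#' Write GWAS summary statistics
#' @param sumstats data.table with snp, a1, a2, z, n (chrom/pos optional)
#' @param path file path
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.table::data.table(SNP = sumstats$snp, A1 = sumstats$a1,
                                A2 = sumstats$a2, Z = sumstats$z,
                                N = sumstats$n)
  if (all(c("chrom", "pos") %in% names(sumstats)))
    out[, `:=`(CHR = sumstats$chrom, BP = sumstats$pos)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write an LD reference bundle
#'
#' A SNP table (`snps.tsv`: SNP, CHR, BP, A1, A2, BLOCK) plus one dense
#' whitespace-delimited correlation matrix per block (`block_<b>.ld`).
#'
#' @param ld an `ld_reference`
#' @param dir output directory (created if needed)
#' @export
write_ld_bundle <- function(ld, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(
    data.table::data.table(SNP = ld$snps$snp, CHR = ld$snps$chrom,
                           BP = ld$snps$pos, A1 = ld$snps$a1,
                           A2 = ld$snps$a2, BLOCK = ld$snps$block),
    file.path(dir, "snps.tsv"), sep = "\t")
  for (b in seq_along(ld$blocks))
    data.table::fwrite(data.table::as.data.table(ld$blocks[[b]]),
                       file.path(dir, sprintf("block_%d.ld", b)),
                       sep = " ", col.names = FALSE)
  invisible(dir)
}

#' Read an LD reference bundle written by [write_ld_bundle()]
#' @param dir bundle directory
#' @return an `ld_reference`
#' @export
read_ld_bundle <- function(dir) {
  st <- data.table::fread(file.path(dir, "snps.tsv"), sep = "\t")
  snps <- data.table::data.table(snp = st$SNP, chrom = st$CHR, pos = st$BP,
                                 a1 = st$A1, a2 = st$A2, block = st$BLOCK)
  blocks <- lapply(sort(unique(snps$block)), function(b)
    as.matrix(data.table::fread(file.path(dir, sprintf("block_%d.ld", b)),
                                sep = " ", header = FALSE)))
  blocks <- lapply(blocks, function(m) { dimnames(m) <- NULL; m })
  structure(list(snps = snps, blocks = blocks), class = "ld_reference")
}

#' Write a SNP-weight bundle
#'
#' A manifest (`manifest.tsv`: PANEL, FEATURE_ID, GENE_ID, CHR, P0, P1,
#' FILE, CISH2) plus one per-feature weight table (SNP, A1, A2, WEIGHT).
#'
#' @param panel a `weight_panel`
#' @param dir output directory
#' @export
write_weight_bundle <- function(panel, dir) {
  dir.create(file.path(dir, "weights"), showWarnings = FALSE,
             recursive = TRUE)
  f <- panel$features
  files <- file.path("weights", paste0(f$feature_id, ".wgt.tsv"))
  data.table::fwrite(
    data.table::data.table(PANEL = f$panel_id, FEATURE_ID = f$feature_id,
                           GENE_ID = f$gene_id, CHR = f$chrom, P0 = f$start,
                           P1 = f$stop, FILE = files, CISH2 = f$cis_h2),
    file.path(dir, "manifest.tsv"), sep = "\t")
  for (i in seq_len(nrow(f))) {
    w <- panel$weights[[i]]
    data.table::fwrite(
      data.table::data.table(SNP = w$snp, A1 = w$a1, A2 = w$a2,
                             WEIGHT = w$weight),
      file.path(dir, files[i]), sep = "\t")
  }
  invisible(dir)
}

#' Read a SNP-weight bundle written by [write_weight_bundle()]
#' @param dir bundle directory
#' @return a `weight_panel`
#' @export
read_weight_bundle <- function(dir) {
  man <- data.table::fread(file.path(dir, "manifest.tsv"), sep = "\t")
  weights <- lapply(seq_len(nrow(man)), function(i) {
    w <- data.table::fread(file.path(dir, man$FILE[i]), sep = "\t")
    data.table::data.table(snp = w$SNP, a1 = w$A1, a2 = w$A2,
                           weight = w$WEIGHT)
  })
  names(weights) <- man$FEATURE_ID
  features <- data.table::data.table(
    feature_id = man$FEATURE_ID, gene_id = man$GENE_ID,
    panel_id = man$PANEL, chrom = man$CHR, start = man$P0, stop = man$P1,
    block = NA_integer_,
    cis_h2 = if ("CISH2" %in% names(man)) man$CISH2 else NA_real_,
    n_snps = vapply(weights, nrow, integer(1)))
  structure(list(features = features, weights = weights),
            class = "weight_panel")
}

#' Fill in the block column of a read-back panel from the LD reference
#' @param panel a `weight_panel` (e.g. from [read_weight_bundle()])
#' @param ld the matching `ld_reference`
#' @return the panel with `features$block` assigned
#' @export
assign_panel_blocks <- function(panel, ld) {
  panel$features$block <- vapply(panel$weights, function(w) {
    b <- unique(ld$snps$block[match(w$snp, ld$snps$snp)])
    b <- b[!is.na(b)]
    if (length(b) != 1L) stop_input("feature spans more than one LD block")
    as.integer(b)
  }, integer(1))
  panel
}

#' Read gene sets from a GMT file
#'
#' Parses with [fgsea::gmtPathways()]; duplicate genes within a set are
#' deduplicated with a warning, empty sets are a format error.
#'
#' @param path GMT file path
#' @return named list of gene-id vectors
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L))
    stop_input("GMT format error: empty gene set")
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate genes within ", sum(dup), " set(s) deduplicated")
    sets[dup] <- lapply(sets[dup], unique)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-id vectors
#' @param path output path
#' @param descriptions optional per-set description column
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-property score table (GENE, STAGE_1..STAGE_k)
#' @param path file path
#' @return data.table with a `gene` column and one numeric column per stage
#' @export
read_property_scores <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (!"GENE" %in% names(dt))
    stop_input("property format error: missing column GENE")
  data.table::setnames(dt, "GENE", "gene")
  dt
}

#' Write a gene-property score table
#' @param properties data.table with `gene` plus stage columns
#' @param path output path
#' @export
write_property_scores <- function(properties, path) {
  out <- data.table::copy(properties)
  data.table::setnames(out, "gene", "GENE")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write per-feature TWAS results
#' @param results output of [twas_scan()]
#' @param path output path
#' @export
write_twas_results <- function(results, path) {
  out <- data.table::data.table(
    PANEL = results$panel, FEATURE_ID = results$feature_id,
    GENE_ID = results$gene_id, CHR = results$chrom, P0 = results$p0,
    P1 = results$p1, NSNPS = results$n_snps, TWAS_Z = results$twas_z,
    TWAS_P = results$twas_p, FDR_P = results$fdr_p)
  if ("tw_sig" %in% names(results)) out[, TW_SIG := results$tw_sig]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
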