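#' Intersect classical and modified eQTL results
#'
#' Returns SNP-probe pairs nominally significant (`p < alpha`) in both
#' scans, classified by the signs of the two coefficients:
#' `flip_neg_to_pos` (classical rho < 0, modified rho > 0),
#' `flip_pos_to_neg` (the reverse), else `concordant`. A rho of exactly 0
#' (degenerate ties) is classed concordant.
#'
#' @param classical,modified `eqtl_result` data.frames from the two scans;
#'   each must have unique (snp_id, probe_id) keys.
#' @param alpha Nominal level (default 0.05).
#' @return data.frame with `snp_id`, `probe_id`, `gene_symbol`,
#'   `rho_classical`, `p_classical`, `rho_modified`, `p_modified`,
#'   `direction`.
#' @export
intersect_pairs <- function(classical, modified, alpha = 0.05) {
  for (nm in list(classical, modified)) {
    key <- paste(nm$snp_id, nm$probe_id)
    if (anyDuplicated(key))
      stop("duplicate (snp, probe) keys within one mode; deduplicate upstream")
  }
  sig <- function(r) r[!is.na(r$p) & r$p < alpha, , drop = FALSE]
  a <- sig(classical); b <- sig(modified)
  m <- merge(
    a[, c("snp_id", "probe_id", "gene_symbol", "rho", "p")],
    b[, c("snp_id", "probe_id", "rho", "p")],
    by = c("snp_id", "probe_id"), suffixes = c("_classical", "_modified"))
  direction <- rep("concordant", nrow(m))
  direction[m$rho_classical < 0 & m$rho_modified > 0] <- "flip_neg_to_pos"
  direction[m$rho_classical > 0 & m$rho_modified < 0] <- "flip_pos_to_neg"
  m$direction <- direction
  m <- m[order(m$gene_symbol, m$snp_id, m$probe_id), ]
  rownames(m) <- NULL
  m
}

#' Genes shared by the two eQTL scans
#'
#' Splits the genes significant in both modes into those carried by shared
#' (identical SNP and probe) pairs and those significant in each mode only
#' through different SNPs/probes.
#'
#' @param classical,modified `eqtl_result` data.frames.
#' @param shared_pairs Output of [intersect_pairs()].
#' @param alpha Nominal level.
#' @return list with character vectors `genes_same_pairs`,
#'   `genes_different_pairs`, `genes_all` (the disjoint union).
#' @export
shared_genes <- function(classical, modified, shared_pairs, alpha = 0.05) {
  sig_genes <- function(r) unique(r$gene_symbol[!is.na(r$p) & r$p < alpha])
  both <- intersect(sig_genes(classical), sig_genes(modified))
  same <- sort(unique(shared_pairs$gene_symbol))
  diff <- sort(setdiff(both, same))
  list(genes_same_pairs = same, genes_different_pairs = diff,
       genes_all = sort(union(same, diff)))
}
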