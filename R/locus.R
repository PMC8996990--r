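#' Map SNPs to genes through flanking windows
#'
#' A SNP at 1-based position P maps to a gene with 0-based half-open body
#' `[start, end)` iff `start - window_bp <= P - 1 < end + window_bp`; a SNP
#' may map to several genes. Windows are symmetric and strand-agnostic.
#' Overlap is computed with GenomicRanges.
#'
#' @param snp_map data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes data.frame with `gene_symbol`, `chrom`, `start`, `end`
#'   (0-based half-open, BED convention).
#' @param window_bp Nonnegative flanking window in bases.
#' @return data.frame with one row per (snp_id, gene_symbol) link.
#' @export
map_snps_to_genes <- function(snp_map, genes, window_bp = 20000L) {
  stopifnot(window_bp >= 0)
  bad <- setdiff(unique(snp_map$chrom), unique(genes$chrom))
  if (length(bad) && !any(snp_map$chrom %in% genes$chrom))
    stop("no shared chromosome names; SNP chroms not in annotation: ",
         paste(bad, collapse = ", "))
  # BED [start,end) 0-based -> 1-based closed [start+1, end], then pad
  g <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start + 1L - window_bp),
                     genes$end + window_bp))
  s <- GenomicRanges::GRanges(snp_map$chrom,
                              IRanges::IRanges(snp_map$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(s, g)
  data.frame(
    snp_id = snp_map$snp_id[S4Vectors::queryHits(ov)],
    gene_symbol = genes$gene_symbol[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
}

#' Case-control association screen
#'
#' Per SNP, fits a logistic model of case status on additive minor-allele
#' dosage adjusted for age and gender, and reports the per-allele odds
#' ratio with its Wald 95% confidence interval. A SNP is flagged
#' significant iff p < `alpha` and the CI excludes OR = 1 (under the Wald
#' construction the two agree; any disagreement would indicate a
#' non-Wald interval and is reported in the `wald_agree` column).
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes A `phenotype_table` with `sample_id`, `status`,
#'   `age`, `gender` for every genotyped sample.
#' @param alpha Nominal level (default 0.05).
#' @return data.frame with columns `snp_id`, `beta`, `or_point`, `ci_low`,
#'   `ci_high`, `p`, `significant`, `skipped`, `skip_reason`, `wald_agree`.
#' @export
association_screen <- function(genotypes, phenotypes, alpha = 0.05) {
  idx <- match(genotypes$sample_ids, phenotypes$sample_id)
  if (anyNA(idx))
    stop("phenotype rows missing for: ",
         paste(utils::head(genotypes$sample_ids[is.na(idx)], 5), collapse = ", "))
  ph <- phenotypes[idx, ]
  y <- as.integer(ph$status == "case")
  age <- ph$age
  male <- as.integer(ph$gender == "male")
  zc <- stats::qnorm(0.975)

  res <- lapply(genotypes$snp_ids, function(s) {
    g <- as.numeric(genotypes$dosages[s, ])
    row <- data.frame(snp_id = s, beta = NA_real_, or_point = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      significant = FALSE, skipped = TRUE,
                      skip_reason = "", wald_agree = NA,
                      stringsAsFactors = FALSE)
    ok <- !is.na(g)
    if (length(unique(g[ok])) < 2L) {
      row$skip_reason <- "constant dosage"
      return(row)
    }
    fit <- suppressWarnings(
      stats::glm(y[ok] ~ g[ok] + age[ok] + male[ok],
                 family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (!"g[ok]" %in% rownames(co)) {
      row$skip_reason <- "dosage dropped (aliased)"
      return(row)
    }
    b <- co["g[ok]", "Estimate"]; se <- co["g[ok]", "Std. Error"]
    if (!is.finite(se) || se > 10 || abs(b) > 15) {
      row$skip_reason <- "separation (unstable estimate)"
      return(row)
    }
    p <- 2 * stats::pnorm(-abs(b / se))
    row$beta <- b; row$or_point <- exp(b)
    row$ci_low <- exp(b - zc * se); row$ci_high <- exp(b + zc * se)
    row$p <- p
    ci_excl <- row$ci_low > 1 || row$ci_high < 1
    row$significant <- (p < alpha) && ci_excl
    row$wald_agree <- (p < alpha) == ci_excl
    row$skipped <- FALSE
    row
  })
  out <- do.call(rbind, res)
  n_dis <- sum(!out$wald_agree, na.rm = TRUE)
  if (n_dis > 0)
    message(n_dis, " SNP(s) where p<alpha and CI-excludes-1 disagree")
  out
}

#' Build the SNP-probe test set for the eQTL scans
#'
#' Joins screen-significant SNPs to their window-mapped genes and those
#' genes' expression probes. Genes without probes drop out. The number of
#' distinct (SNP, probe) pairs defines the Bonferroni denominator for the
#' scans.
#'
#' @param mapping Output of [map_snps_to_genes()].
#' @param screen Output of [association_screen()] (or any data.frame with
#'   `snp_id` and logical `significant`).
#' @param probe_map data.frame with `probe_id`, `gene_symbol`.
#' @return data.frame `snp_id`, `probe_id`, `gene_symbol`, deduplicated.
#' @export
select_test_set <- function(mapping, screen, probe_map) {
  sig <- screen$snp_id[!is.na(screen$significant) & screen$significant]
  if (!length(sig)) {
    warning("no screen-significant SNPs; empty test set")
    return(data.frame(snp_id = character(), probe_id = character(),
                      gene_symbol = character(), stringsAsFactors = FALSE))
  }
  m <- mapping[mapping$snp_id %in% sig, , drop = FALSE]
  j <- merge(m, probe_map, by = "gene_symbol")
  j <- unique(j[, c("snp_id", "probe_id", "gene_symbol")])
  j <- j[order(j$snp_id, j$probe_id), ]
  rownames(j) <- NULL
  j
}
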