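#' Spearman rank-correlation test
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks
#' (ties get mean rank) after dropping incomplete pairs, with a two-sided
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' `rho = +/-1` yields `p = 0` by convention.
#'
#' @param x,y Paired numeric vectors (dosages and signals); pairs with a
#'   missing entry in either are dropped.
#' @param min_n Minimum complete pairs required (default 3).
#' @return list with `rho`, `p`, `n_used`, and `skipped`/`skip_reason`
#'   (non-empty when the test cannot be run: too few pairs or a constant
#'   vector).
#' @examples
#' spearman_test(c(0, 1, 2, 0, 1, 2), c(1.1, 2.0, 3.2, 0.9, 2.1, 3.0))
#' @export
spearman_test <- function(x, y, min_n = 3L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  skip <- function(reason) list(rho = NA_real_, p = NA_real_, n_used = n,
                                skipped = TRUE, skip_reason = reason)
  if (n < min_n) return(skip(sprintf("n_used=%d < %d", n, min_n)))
  if (length(unique(x)) < 2L) return(skip("constant x"))
  if (length(unique(y)) < 2L) return(skip("constant y"))
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_rho_pvalue(rho, n)
  list(rho = rho, p = p, n_used = n, skipped = FALSE, skip_reason = "")
}

#' Two-sided p-value for a Spearman rho via the t approximation
#'
#' @param rho Spearman coefficient(s) in \[-1, 1\].
#' @param n Number of paired observations used (n >= 3).
#' @return Two-sided p-value(s); exactly 0 when `|rho| = 1`.
#' @examples
#' spearman_rho_pvalue(-0.365, 100)  # ~2e-4
#' @export
spearman_rho_pvalue <- function(rho, n) {
  stopifnot(all(abs(rho) <= 1 + 1e-12), all(n >= 3))
  rho <- pmin(1, pmax(-1, rho))
  p <- ifelse(abs(rho) == 1, 0, {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  })
  unname(p)
}

eqtl_scan <- function(genotypes, expression, pairs, mode, min_n = 3L) {
  stopifnot(mode %in% c("classical", "modified"))
  cases <- intersect(expression$case_ids, genotypes$sample_ids)
  ymat <- if (mode == "classical") expression$normal_log2
          else expression$tumor_log2 - expression$normal_log2
  empty <- data.frame(snp_id = character(), probe_id = character(),
                      gene_symbol = character(), mode = character(),
                      rho = numeric(), p = numeric(), n_used = integer(),
                      skipped = logical(), skip_reason = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    class(empty) <- c("eqtl_result", "data.frame")
    return(empty)
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    snp <- pairs$snp_id[i]; probe <- pairs$probe_id[i]
    row <- data.frame(snp_id = snp, probe_id = probe,
                      gene_symbol = pairs$gene_symbol[i], mode = mode,
                      rho = NA_real_, p = NA_real_, n_used = NA_integer_,
                      skipped = TRUE, skip_reason = "",
                      stringsAsFactors = FALSE)
    if (!probe %in% rownames(ymat)) {
      row$skip_reason <- "probe absent from expression matrix"
    } else if (!snp %in% rownames(genotypes$dosages)) {
      row$skip_reason <- "SNP absent from genotype matrix"
    } else {
      st <- spearman_test(as.numeric(genotypes$dosages[snp, cases]),
                          as.numeric(ymat[probe, cases]), min_n = min_n)
      row$rho <- st$rho; row$p <- st$p; row$n_used <- st$n_used
      row$skipped <- st$skipped; row$skip_reason <- st$skip_reason
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  class(res) <- c("eqtl_result", "data.frame")
  res
}

#' Classical eQTL scan (normal-tissue signal)
#'
#' One Spearman test per selected SNP-probe pair using the normal-layer
#' log2 signal as phenotype.
#'
#' @param genotypes A `genotype_matrix`.
#' @param expression A `paired_expression`.
#' @param pairs Test set from [select_test_set()].
#' @param min_n Minimum complete pairs per test.
#' @return data.frame of class `eqtl_result`: `snp_id`, `probe_id`,
#'   `gene_symbol`, `mode`, `rho`, `p`, `n_used`, `skipped`, `skip_reason`.
#' @export
classical_scan <- function(genotypes, expression, pairs, min_n = 3L)
  eqtl_scan(genotypes, expression, pairs, "classical", min_n)

#' Modified eQTL scan (tumor/normal log2 fold change)
#'
#' As [classical_scan()], with the per-case phenotype
#' `tumor_log2 - normal_log2` (the paired log2 fold change).
#'
#' @inheritParams classical_scan
#' @return data.frame of class `eqtl_result` with `mode = "modified"`.
#' @export
modified_scan <- function(genotypes, expression, pairs, min_n = 3L)
  eqtl_scan(genotypes, expression, pairs, "modified", min_n)

#' Summarize an eQTL scan
#'
#' @param results An `eqtl_result` data.frame (skipped tests still count
#'   toward the number of tests attempted).
#' @param alpha Nominal level (default 0.05); significance is strict
#'   `p < alpha`.
#' @return list with `m_tests`, `alpha`, `bonferroni_threshold`
#'   (= alpha/m_tests exactly) and `n_significant`.
#' @export
summarize_scan <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("empty result set")
  m <- nrow(results)
  list(m_tests = m, alpha = alpha,
       bonferroni_threshold = alpha / m,
       n_significant = sum(!is.na(results$p) & results$p < alpha))
}
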