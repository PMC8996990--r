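#' Paired tumor-vs-normal differential expression
#'
#' Per probe, a paired two-sided t-test on the per-case log2 differences
#' `tumor - normal`, with Benjamini-Hochberg adjustment across all tested
#' probes. Probes whose differences have zero variance are skipped (their
#' q-value stays NA and they do not enter the BH family).
#'
#' @param expression A `paired_expression`.
#' @param probe_map Optional `probe_id`/`gene_symbol` map to attach gene
#'   symbols.
#' @return data.frame: `probe_id`, `gene_symbol`, `mean_log2fc`,
#'   `t_statistic`, `p`, `fdr_q`, `skipped`.
#' @export
paired_deg <- function(expression, probe_map = NULL) {
  d <- expression$tumor_log2 - expression$normal_log2
  n <- ncol(d)
  if (n < 3) stop("need >= 3 paired cases")
  res <- data.frame(probe_id = rownames(d),
                    gene_symbol = NA_character_,
                    mean_log2fc = rowMeans(d),
                    t_statistic = NA_real_, p = NA_real_, fdr_q = NA_real_,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(d))) {
    v <- d[i, ]
    if (stats::sd(v) == 0) {
      if (all(v == 0)) {  # identical layers: t = 0, p = 1 by convention
        res$t_statistic[i] <- 0; res$p[i] <- 1
      } else res$skipped[i] <- TRUE
      next
    }
    tt <- stats::t.test(v)
    res$t_statistic[i] <- unname(tt$statistic)
    res$p[i] <- tt$p.value
  }
  tested <- !is.na(res$p)
  res$fdr_q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  if (!is.null(probe_map)) {
    idx <- match(res$probe_id, probe_map$probe_id)
    res$gene_symbol <- probe_map$gene_symbol[idx]
  }
  res
}

#' Median-split Kaplan-Meier log-rank test
#'
#' Splits cases at the median of a per-case value (ties go to the low
#' group) and compares the two survival curves with the log-rank test
#' (via `survival::survdiff`).
#'
#' @param phenotypes A `phenotype_table`; only rows with non-missing
#'   survival are used.
#' @param values Named numeric vector (names = sample ids) of the
#'   stratifying quantity, e.g. one gene's normal expression, tumor
#'   expression, or log2 fold change.
#' @param stratifier Label recorded in the output (e.g.
#'   "normal_expression").
#' @return list: `stratifier`, `split` ("median"), `n_low`, `n_high`,
#'   `logrank_statistic` (chi-squared, 1 df), `p`.
#' @export
km_logrank <- function(phenotypes, values, stratifier = "value") {
  ph <- phenotypes[!is.na(phenotypes$survival_months) &
                     !is.na(phenotypes$event), , drop = FALSE]
  common <- intersect(ph$sample_id, names(values))
  if (length(common) < 4) stop("need >= 4 cases with survival and values")
  ph <- ph[match(common, ph$sample_id), ]
  v <- values[common]
  if (length(unique(v)) < 2) stop("all stratifier values identical; no split")
  grp <- factor(ifelse(v <= stats::median(v), "low", "high"),
                levels = c("low", "high"))
  if (any(table(grp) < 2)) stop("median split leaves a group with < 2 cases")
  sd <- survival::survdiff(
    survival::Surv(ph$survival_months, ph$event) ~ grp)
  chisq <- unname(sd$chisq)
  list(stratifier = stratifier, split = "median",
       n_low = sum(grp == "low"), n_high = sum(grp == "high"),
       logrank_statistic = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Survival screen over genes and stratifiers
#'
#' Runs [km_logrank()] for each gene under the three stratifiers used for
#' shared-gene characterization: normal expression, tumor expression and
#' log2 fold change (gene value = mean over its probes).
#'
#' @param phenotypes A `phenotype_table`.
#' @param expression A `paired_expression`.
#' @param probe_map `probe_id`/`gene_symbol` map.
#' @param genes Genes to test (default: all in `probe_map`).
#' @return data.frame: `gene_symbol`, `stratifier`, `logrank_statistic`,
#'   `p` (NA with a `note` when a gene/stratifier could not be tested).
#' @export
survival_screen <- function(phenotypes, expression, probe_map,
                            genes = unique(probe_map$gene_symbol)) {
  layers <- list(
    normal_expression = expression$normal_log2,
    tumor_expression = expression$tumor_log2,
    fold_change = expression$tumor_log2 - expression$normal_log2)
  out <- list()
  for (g in genes) {
    pr <- intersect(probe_map$probe_id[probe_map$gene_symbol == g],
                    expression$probe_ids)
    if (!length(pr)) next
    for (lab in names(layers)) {
      v <- colMeans(layers[[lab]][pr, , drop = FALSE])
      row <- data.frame(gene_symbol = g, stratifier = lab,
                        logrank_statistic = NA_real_, p = NA_real_,
                        note = "", stringsAsFactors = FALSE)
      r <- tryCatch(km_logrank(phenotypes, v, lab), error = function(e) e)
      if (inherits(r, "error")) row$note <- conditionMessage(r)
      else {
        row$logrank_statistic <- r$logrank_statistic
        row$p <- r$p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
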