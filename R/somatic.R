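#' Default somatic calling thresholds
#'
#' @param logr_gain Tumor logR above which a SNP is called copy-number
#'   gain (default +0.2).
#' @param logr_loss Tumor logR below which a SNP is called loss
#'   (default -0.2).
#' @param baf_ai_dev Minimum |BAF - 0.5| at a germline-het SNP for an
#'   allelic-imbalance flag (default 0.2).
#' @param baf_loh BAF at or beyond which (>= `baf_loh` or <= 1 - `baf_loh`)
#'   a germline-het SNP with nonpositive logR is flagged LOH (default 0.85).
#' @return Named list of thresholds.
#' @export
somatic_thresholds <- function(logr_gain = 0.2, logr_loss = -0.2,
                               baf_ai_dev = 0.2, baf_loh = 0.85) {
  stopifnot(logr_gain > logr_loss, baf_ai_dev > 0, baf_loh > 0.5,
            baf_loh <= 1)
  list(logr_gain = logr_gain, logr_loss = logr_loss,
       baf_ai_dev = baf_ai_dev, baf_loh = baf_loh)
}

#' Per-SNP somatic state calls from paired array signals
#'
#' Copy-number state comes from tumor logR thresholds. Allelic flags are
#' informative only at germline-heterozygous SNPs: LOH when tumor BAF is
#' pushed to a homozygous value (`>= baf_loh` or `<= 1 - baf_loh`) with
#' logR <= 0; allelic imbalance when `|BAF - 0.5| > baf_ai_dev` and the
#' SNP is not LOH.
#'
#' @param signal An `array_signal` (see [simulate_somatic()] or
#'   [read_array_signal_tsv()]).
#' @param thresholds A [somatic_thresholds()] list.
#' @return data.frame with one row per SNP x case: `snp_id`, `case_id`,
#'   `cn_state` (gain/loss/neutral), `ai_flag`, `loh_flag`
#'   (yes/no/uninformative).
#' @export
call_snp_states <- function(signal, thresholds = somatic_thresholds()) {
  baf <- signal$tumor_baf
  if (any(baf < 0 | baf > 1, na.rm = TRUE))
    stop("BAF outside [0, 1]")
  logr <- signal$tumor_logr
  germ <- signal$germline_genotype
  ns <- nrow(logr); nc <- ncol(logr)

  cn <- matrix("neutral", ns, nc)
  cn[logr > thresholds$logr_gain] <- "gain"
  cn[logr < thresholds$logr_loss] <- "loss"

  het <- !is.na(germ) & germ == 1L & !is.na(baf)
  loh <- matrix("uninformative", ns, nc)
  ai <- matrix("uninformative", ns, nc)
  is_loh <- het & (baf >= thresholds$baf_loh | baf <= 1 - thresholds$baf_loh) &
    logr <= 0
  is_ai <- het & abs(baf - 0.5) > thresholds$baf_ai_dev & !is_loh
  loh[het] <- ifelse(is_loh[het], "yes", "no")
  ai[het] <- ifelse(is_ai[het], "yes", "no")

  data.frame(
    snp_id = rep(signal$snp_ids, nc),
    case_id = rep(signal$case_ids, each = ns),
    cn_state = as.vector(cn), ai_flag = as.vector(ai),
    loh_flag = as.vector(loh), stringsAsFactors = FALSE)
}

#' Aggregate SNP calls to per-gene somatic alteration categories
#'
#' Over the SNPs in each gene's flanking window, per case: category `gain`
#' if at least `min_fraction` of CN-informative SNPs are gain; else
#' `loss_or_loh` if at least `min_fraction` are loss OR any het SNP is
#' LOH-flagged; else `ai_only` if any het SNP is AI-flagged; else `none`.
#' Precedence gain > loss_or_loh > ai_only mirrors a mutually exclusive
#' frequency-table layout. `with_ai` marks gain/loss_or_loh calls that also
#' carry an AI flag.
#'
#' @param snp_calls Output of [call_snp_states()].
#' @param mapping SNP-to-gene window mapping from [map_snps_to_genes()].
#' @param min_fraction Fraction of CN-informative SNPs required for a CN
#'   call, in (0, 1] (default 0.5).
#' @return data.frame: `gene_symbol`, `case_id`, `category`
#'   (none/ai_only/gain/loss_or_loh), `with_ai`, `n_snps` (informative
#'   SNPs used).
#' @export
call_gene_alterations <- function(snp_calls, mapping, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  genes <- unique(mapping$gene_symbol)
  cases <- unique(snp_calls$case_id)
  calls_by_snp <- split(seq_len(nrow(snp_calls)), snp_calls$snp_id)
  out <- vector("list", length(genes) * length(cases))
  k <- 0L
  for (g in genes) {
    snps <- mapping$snp_id[mapping$gene_symbol == g]
    rows <- unlist(calls_by_snp[snps], use.names = FALSE)
    sub <- snp_calls[rows, , drop = FALSE]
    for (cs in cases) {
      sc <- sub[sub$case_id == cs, , drop = FALSE]
      k <- k + 1L
      out[[k]] <- gene_call_one(g, cs, sc$cn_state, sc$ai_flag, sc$loh_flag,
                                min_fraction)
    }
  }
  do.call(rbind, out)
}

# single gene x case aggregation; kept straight-line for auditability
gene_call_one <- function(gene, case, cn, ai, loh, min_fraction) {
  n <- length(cn)
  any_ai <- any(ai == "yes")
  category <-
    if (n == 0) "none"
    else if (mean(cn == "gain") >= min_fraction) "gain"
    else if (mean(cn == "loss") >= min_fraction || any(loh == "yes"))
      "loss_or_loh"
    else if (any_ai) "ai_only"
    else "none"
  data.frame(gene_symbol = gene, case_id = case, category = category,
             with_ai = category %in% c("gain", "loss_or_loh") && any_ai,
             n_snps = n, stringsAsFactors = FALSE)
}

#' Per-gene, per-case expression abnormality
#'
#' Averages the tumor-vs-normal log2 fold change over a gene's probes and
#' thresholds it: `over` when mean log2FC >= `fc_threshold`, `under` when
#' <= -`fc_threshold`, else `normal`.
#'
#' @param expression A `paired_expression`.
#' @param probe_map data.frame `probe_id`, `gene_symbol`.
#' @param fc_threshold Positive log2 fold-change threshold (default 1,
#'   i.e. two-fold).
#' @return data.frame: `gene_symbol`, `case_id`, `log2fc`, `status`.
#' @export
expression_abnormality <- function(expression, probe_map, fc_threshold = 1) {
  stopifnot(fc_threshold > 0)
  fc <- expression$tumor_log2 - expression$normal_log2
  pm <- probe_map[probe_map$probe_id %in% rownames(fc), , drop = FALSE]
  genes <- unique(pm$gene_symbol)
  out <- lapply(genes, function(g) {
    rows <- pm$probe_id[pm$gene_symbol == g]
    m <- colMeans(fc[rows, , drop = FALSE])
    data.frame(gene_symbol = g, case_id = colnames(fc), log2fc = unname(m),
               status = ifelse(m >= fc_threshold, "over",
                               ifelse(m <= -fc_threshold, "under", "normal")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort frequency table of expression and somatic alteration
#'
#' One row per gene: over/under/abnormal expression frequencies over the
#' expression cohort, and AI-only / CN gain / CN loss-or-LOH / total
#' alteration frequencies over the (possibly smaller) array cohort.
#' Frequencies are unrounded fractions; `freq_abnormal = freq_over +
#' freq_under` and `freq_total = freq_ai_only + freq_gain + freq_loss_loh`
#' hold exactly.
#'
#' @param gene_calls Output of [call_gene_alterations()].
#' @param abnormality Output of [expression_abnormality()].
#' @return data.frame with the frequency columns plus cohort sizes
#'   `n_expr`, `n_array`.
#' @export
frequency_table <- function(gene_calls, abnormality) {
  genes <- sort(union(unique(gene_calls$gene_symbol),
                      unique(abnormality$gene_symbol)))
  n_expr <- length(unique(abnormality$case_id))
  n_array <- length(unique(gene_calls$case_id))
  out <- lapply(genes, function(g) {
    ab <- abnormality[abnormality$gene_symbol == g, , drop = FALSE]
    gc <- gene_calls[gene_calls$gene_symbol == g, , drop = FALSE]
    f_over <- if (n_expr) sum(ab$status == "over") / n_expr else 0
    f_under <- if (n_expr) sum(ab$status == "under") / n_expr else 0
    f_ai <- if (n_array) sum(gc$category == "ai_only") / n_array else 0
    f_gain <- if (n_array) sum(gc$category == "gain") / n_array else 0
    f_ll <- if (n_array) sum(gc$category == "loss_or_loh") / n_array else 0
    data.frame(gene_symbol = g,
               freq_over = f_over, freq_under = f_under,
               freq_abnormal = f_over + f_under,
               freq_ai_only = f_ai, freq_gain = f_gain,
               freq_loss_loh = f_ll, freq_total = f_ai + f_gain + f_ll,
               n_expr = n_expr, n_array = n_array,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
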