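#' Simulate gene annotation, pathway membership and probe map
#'
#' Lays `n_genes` genes along one synthetic chromosome (200 kb apart, 20 kb
#' long, coordinates 0-based half-open as in BED), assigns each gene to one
#' or two of the pathways (inflammation, DNA repair, immunity), and gives
#' each gene one or two expression probes.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `gene_annotation` with columns
#'   `gene_symbol`, `chrom`, `start`, `end`, `pathways`
#'   (comma-separated), and `probes` (comma-separated probe ids).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "annotation"))
  n <- config$n_genes
  sym <- sprintf("GENE%03d", seq_len(n))
  start <- 100000L + (seq_len(n) - 1L) * 200000L
  end <- start + 20000L
  paths <- c("inflammation", "dna_repair", "immunity")
  pathways <- paths[(seq_len(n) - 1L) %% 3L + 1L]
  # roughly a third of genes sit in two pathways
  two <- seq_len(n) %% 3L == 0L
  pathways[two] <- paste(pathways[two], paths[seq_len(n)[two] %% 3L + 1L],
                         sep = ",")
  n_probes <- rep_len(c(1L, 2L), n)
  probes <- vapply(seq_len(n), function(i)
    paste(sprintf("%s_p%d", sym[i], seq_len(n_probes[i])), collapse = ","),
    character(1))
  ann <- data.frame(gene_symbol = sym, chrom = "chr1", start = start,
                    end = end, pathways = pathways, probes = probes,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Probe-to-gene map from an annotation table
#'
#' @param annotation A [simulate_annotation()] table (or any data.frame with
#'   `gene_symbol` and comma-separated `probes`).
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
probe_map <- function(annotation) {
  pr <- strsplit(annotation$probes, ",", fixed = TRUE)
  data.frame(probe_id = unlist(pr),
             gene_symbol = rep(annotation$gene_symbol, lengths(pr)),
             stringsAsFactors = FALSE)
}

sim_sample_ids <- function(config) {
  list(cases = sprintf("case_%04d", seq_len(config$n_cases)),
       controls = sprintf("ctrl_%04d", seq_len(config$n_controls)))
}

#' Simulate a case-control genotype matrix under Hardy-Weinberg equilibrium
#'
#' Control genotypes are drawn under HWE at each SNP's MAF; case genotypes
#' follow the retrospective-sampling distribution of a logistic disease
#' model, `P(G = g | case) proportional to HWE(g) * exp(b * g)` with `b` the
#' SNP's planted per-allele log odds (0 unless listed in
#' `config$effect_table`). SNP positions are placed so that every gene
#' window from [simulate_annotation()] contains at least one SNP; leftover
#' SNPs are spread uniformly over the chromosome.
#'
#' @param config A [sim_config()].
#' @param annotation Optional annotation table; defaults to
#'   `simulate_annotation(config)`.
#' @return A `genotype_matrix`: list with `dosages` (SNPs x samples integer
#'   matrix in \{0,1,2,NA\}), `sample_ids`, `snp_ids`, and `snp_map`
#'   (data.frame `snp_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `maf`).
#' @export
simulate_genotypes <- function(config, annotation = simulate_annotation(config)) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "genotypes"))
  ids <- sim_sample_ids(config)
  samples <- c(ids$cases, ids$controls)
  n_snps <- config$n_snps
  if (n_snps < config$n_genes)
    stop("n_snps must be >= n_genes so every gene window is covered")

  # one anchor SNP mid-gene per gene, remainder uniform over the span
  anchor <- as.integer((annotation$start + annotation$end) / 2)
  span <- c(1L, max(annotation$end) + config$window_bp + 100000L)
  extra <- sort(sample(span[1]:span[2], n_snps - config$n_genes))
  pos <- sort(c(anchor, extra))
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  maf <- runif(n_snps, config$maf_range[1], config$maf_range[2])

  log_odds <- setNames(rep(0, n_snps), snp_ids)
  if (!is.null(config$effect_table)) {
    unknown <- setdiff(config$effect_table$snp_id, snp_ids)
    if (length(unknown))
      stop("effect_table SNP(s) not in panel: ", paste(unknown, collapse = ", "))
    log_odds[config$effect_table$snp_id] <- config$effect_table$case_control_log_odds
  }

  dos <- matrix(NA_integer_, nrow = n_snps, ncol = length(samples),
                dimnames = list(snp_ids, samples))
  is_case <- samples %in% ids$cases
  for (j in seq_len(n_snps)) {
    q <- maf[j]
    hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    pcase <- hwe * exp(log_odds[j] * 0:2)
    dos[j, !is_case] <- sample(0:2, sum(!is_case), TRUE, prob = hwe)
    dos[j, is_case] <- sample(0:2, sum(is_case), TRUE, prob = pcase / sum(pcase))
  }
  if (config$missing_rate > 0) {
    miss <- runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_integer_
  }
  structure(list(
    dosages = dos, sample_ids = samples, snp_ids = snp_ids,
    snp_map = data.frame(snp_id = snp_ids, chrom = "chr1", pos = pos,
                         ref = "A", alt = "G", maf = maf,
                         stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$snp_ids), "SNPs x",
      length(x$sample_ids), "samples;",
      sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' Simulate paired normal/tumor log2 expression
#'
#' Normal-layer signal is `baseline + beta_normal * dosage + noise`; the
#' tumor layer is `baseline + tumor_shift + beta_tumor * dosage + noise`
#' with independent noise, both on the log2 scale. Planted per-allele
#' effects from `config$effect_table` are applied to the probes of every
#' gene whose flanking window contains the SNP, so a SNP with
#' `beta_normal != 0, beta_tumor = 0` produces, by construction, a
#' classical eQTL and an opposite-sign fold-change (modified) eQTL.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param annotation The matching [simulate_annotation()] table.
#' @param config A [sim_config()].
#' @return A `paired_expression`: list with `normal_log2` and `tumor_log2`
#'   (probes x cases matrices sharing dimnames), `probe_ids`, `case_ids`,
#'   and `baseline` (per-probe).
#' @export
simulate_expression <- function(genotypes, annotation, config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "expression"))
  cases <- sim_sample_ids(config)$cases[seq_len(config$n_expr_cases)]
  pm <- probe_map(annotation)
  probes <- pm$probe_id
  np <- length(probes); nc <- length(cases)

  baseline <- rnorm(np, config$baseline_mean, config$baseline_sd)
  shift <- config$tumor_shift
  shift_vec <- if (length(shift) == 1L && is.null(names(shift)))
    rep(as.numeric(shift), np)
  else {
    s <- setNames(rep(0, np), pm$gene_symbol)
    hit <- pm$gene_symbol %in% names(shift)
    s[hit] <- shift[pm$gene_symbol[hit]]
    as.numeric(s)
  }

  normal <- matrix(baseline, np, nc) +
    matrix(rnorm(np * nc, 0, config$noise_sd), np, nc)
  tumor <- matrix(baseline + shift_vec, np, nc) +
    matrix(rnorm(np * nc, 0, config$noise_sd), np, nc)
  dimnames(normal) <- dimnames(tumor) <- list(probes, cases)

  if (!is.null(config$effect_table)) {
    et <- config$effect_table
    unknown <- setdiff(et$snp_id, genotypes$snp_ids)
    if (length(unknown))
      stop("effect_table SNP(s) not in genotypes: ",
           paste(unknown, collapse = ", "))
    snp2gene <- map_snps_to_genes(genotypes$snp_map, annotation,
                                  config$window_bp)
    for (i in seq_len(nrow(et))) {
      g <- dose_numeric(genotypes$dosages[et$snp_id[i], cases])
      g[is.na(g)] <- 0  # missing genotype carries no planted effect
      genes_hit <- snp2gene$gene_symbol[snp2gene$snp_id == et$snp_id[i]]
      if (!length(genes_hit)) {
        warning("effect SNP ", et$snp_id[i], " maps to no gene window")
        next
      }
      rows <- pm$probe_id[pm$gene_symbol %in% genes_hit]
      for (pr in rows) {
        normal[pr, ] <- normal[pr, ] + et$beta_normal[i] * g
        tumor[pr, ] <- tumor[pr, ] + et$beta_tumor[i] * g
      }
    }
  }
  structure(list(normal_log2 = normal, tumor_log2 = tumor,
                 probe_ids = probes, case_ids = cases, baseline = baseline),
            class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("paired_expression:", length(x$probe_ids), "probes x",
      length(x$case_ids), "paired cases (normal + tumor log2 layers)\n")
  invisible(x)
}

dose_numeric <- function(x) as.numeric(x)

#' Simulate paired tumor/germline SNP-array signals
#'
#' For each gene and array case a latent somatic state is drawn from
#' `config$somatic_rates` (`gain`, `loss`, `loh`, `ai`, remainder `none`).
#' All SNPs inside the gene's flanking window then receive tumor logR and
#' BAF consistent with that state:
#' \itemize{
#'   \item `gain`: logR centered at `logr_gain_mean`; germline-het BAF
#'     splits to 1/3 or 2/3 (one parental allele duplicated);
#'   \item `loss`: logR centered at `logr_loss_mean`; het BAF collapses to
#'     0 or 1 (LOH by deletion);
#'   \item `loh`: copy-neutral LOH, logR centered at 0 with het BAF at 0/1;
#'   \item `ai`: logR centered at 0 with het BAF displaced to 0.25/0.75;
#'   \item `none`: logR centered at 0, het BAF at 0.5.
#' }
#' Germline-homozygous SNPs keep BAF near 0 or 1 in every state. SNPs
#' outside all gene windows behave as `none`.
#'
#' @param genotypes A [simulate_genotypes()] result (germline genotypes).
#' @param annotation The matching annotation table.
#' @param config A [sim_config()].
#' @return An `array_signal`: list with `tumor_logr`, `tumor_baf`,
#'   `germline_genotype` (SNPs x array-cases matrices), `snp_ids`,
#'   `case_ids`, and `latent_states` (genes x cases character matrix, the
#'   simulation truth used by round-trip tests).
#' @export
simulate_somatic <- function(genotypes, annotation, config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "somatic"))
  cases <- sim_sample_ids(config)$cases[seq_len(config$n_array_cases)]
  snps <- genotypes$snp_ids
  ns <- length(snps); nc <- length(cases)
  germ <- genotypes$dosages[, cases, drop = FALSE]

  snp2gene <- map_snps_to_genes(genotypes$snp_map, annotation, config$window_bp)
  uncovered <- setdiff(annotation$gene_symbol, snp2gene$gene_symbol)
  if (length(uncovered))
    warning("gene(s) with no SNP in window; somatic state unobservable: ",
            paste(uncovered, collapse = ", "))

  rates <- somatic_rate_table(config$somatic_rates, annotation$gene_symbol)
  states <- c("gain", "loss", "loh", "ai", "none")
  latent <- matrix("none", nrow = nrow(annotation), ncol = nc,
                   dimnames = list(annotation$gene_symbol, cases))
  for (i in seq_len(nrow(annotation))) {
    p <- c(rates$gain[i], rates$loss[i], rates$loh[i], rates$ai[i])
    latent[i, ] <- sample(states, nc, TRUE, prob = c(p, 1 - sum(p)))
  }

  logr <- matrix(rnorm(ns * nc, 0, config$signal_sd), ns, nc,
                 dimnames = list(snps, cases))
  # baseline BAF from germline genotype
  baf <- matrix(NA_real_, ns, nc, dimnames = list(snps, cases))
  target <- matrix(NA_real_, ns, nc)
  target[] <- c(0, 0.5, 1)[germ + 1L]

  for (i in seq_len(nrow(annotation))) {
    gsym <- annotation$gene_symbol[i]
    rows <- snp2gene$snp_id[snp2gene$gene_symbol == gsym]
    if (!length(rows)) next
    for (j in seq_len(nc)) {
      st <- latent[gsym, j]
      if (st == "none") next
      het <- which(!is.na(germ[rows, j]) & germ[rows, j] == 1L)
      if (st == "gain") {
        logr[rows, j] <- rnorm(length(rows), config$logr_gain_mean,
                               config$signal_sd)
        if (length(het))
          target[match(rows, snps)[het], j] <-
            sample(c(1 / 3, 2 / 3), length(het), TRUE)
      } else if (st == "loss" || st == "loh") {
        if (st == "loss")
          logr[rows, j] <- rnorm(length(rows), config$logr_loss_mean,
                                 config$signal_sd)
        if (length(het)) {
          kept <- sample(c(0, 1), 1)  # which allele survives, per gene-case
          target[match(rows, snps)[het], j] <- kept
        }
      } else if (st == "ai") {
        if (length(het))
          target[match(rows, snps)[het], j] <-
            sample(c(0.25, 0.75), length(het), TRUE)
      }
    }
  }
  baf[] <- pmin(1, pmax(0, target + rnorm(ns * nc, 0, config$baf_sd)))
  baf[is.na(germ)] <- NA_real_

  structure(list(tumor_logr = logr, tumor_baf = baf,
                 germline_genotype = germ, snp_ids = snps, case_ids = cases,
                 latent_states = latent),
            class = "array_signal")
}

#' Simulate phenotypes and expression-dependent survival
#'
#' Builds the sample phenotype table (case/control status, age uniform on
#' 39-71 years, 60% male) and draws exponential survival times for cases:
#' the per-case rate is `log(2)/median_survival_months *
#' exp(hazard_coef * z)` where `z` is the centered normal-layer expression
#' of the survival probe (0 for cases without expression data). Each case
#' is independently right-censored with probability `censor_rate`
#' (censoring time uniform on (0, event time)).
#'
#' @param expression A [simulate_expression()] result.
#' @param config A [sim_config()].
#' @return A `phenotype_table` data.frame: `sample_id`, `status`
#'   (case/control), `age`, `gender`, `survival_months` (cases only, NA for
#'   controls), `event` (1 death observed, 0 censored, NA for controls).
#' @export
simulate_survival <- function(expression, config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "survival"))
  ids <- sim_sample_ids(config)
  samples <- c(ids$cases, ids$controls)
  n <- length(samples)
  status <- ifelse(samples %in% ids$cases, "case", "control")
  age <- sample(39:71, n, TRUE)
  gender <- sample(c("male", "female"), n, TRUE, prob = c(0.6, 0.4))

  probe <- config$survival_probe
  if (is.null(probe)) probe <- expression$probe_ids[1]
  if (!probe %in% expression$probe_ids)
    stop("survival_probe not in expression matrix: ", probe)
  z <- setNames(rep(0, n), samples)
  ev <- expression$normal_log2[probe, ]
  z[expression$case_ids] <- ev - mean(ev)

  base_rate <- log(2) / config$median_survival_months
  surv <- rep(NA_real_, n); event <- rep(NA_integer_, n)
  is_case <- status == "case"
  rate <- base_rate * exp(config$hazard_coef * z[is_case])
  t_event <- rexp(sum(is_case), rate)
  cens <- runif(sum(is_case)) < config$censor_rate
  t_obs <- ifelse(cens, runif(sum(is_case)) * t_event, t_event)
  surv[is_case] <- pmax(0.1, round(t_obs, 1))
  event[is_case] <- as.integer(!cens)

  out <- data.frame(sample_id = samples, status = status, age = age,
                    gender = gender, survival_months = surv, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}
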