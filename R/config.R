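#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. Defaults reproduce the structure of the study
#' design the package targets: a case-control genotyping cohort
#' (1423 cases / 1660 controls), a paired tumor/normal expression cohort of
#' 100 cases (a subset of the genotyped cases), and a paired-array somatic
#' cohort of 76 cases (a subset of the expression cases), with SNPs mapped
#' to pathway genes through +/- 20 kb windows.
#'
#' @param n_cases,n_controls Genotyping cohort sizes.
#' @param n_expr_cases Number of cases with paired tumor/normal expression;
#'   must not exceed `n_cases`.
#' @param n_array_cases Number of cases with paired tumor/germline SNP-array
#'   signals; must not exceed `n_expr_cases`.
#' @param n_snps,n_genes Panel sizes. Every gene is guaranteed at least one
#'   SNP inside its flanking window.
#' @param maf_range Minor-allele-frequency range, each endpoint in (0, 0.5].
#'   Per-SNP MAFs are drawn uniformly on this range.
#' @param window_bp Flanking window in bases added on each side of a gene
#'   when mapping SNPs to genes (default 20000).
#' @param effect_table `NULL`, or a data.frame with columns `snp_id`,
#'   `beta_normal`, `beta_tumor` (log2-units of expression per minor allele,
#'   applied to the probes of the gene(s) whose window contains the SNP) and
#'   `case_control_log_odds` (per-allele disease log odds).
#' @param noise_sd Additive Gaussian noise SD on the log2 expression scale,
#'   shared across probes and layers.
#' @param tumor_shift Tumor-vs-normal mean log2 shift; a scalar applied to
#'   all probes, or a named vector keyed by gene symbol.
#' @param baseline_mean,baseline_sd Per-probe baseline log2 signal
#'   distribution.
#' @param somatic_rates Per-gene latent somatic state probabilities: a named
#'   numeric vector with entries `gain`, `loss`, `loh`, `ai` applied to all
#'   genes, or a data.frame with a `gene_symbol` column plus those four
#'   columns. Probabilities must be in [0,1] and sum to at most 1 per gene;
#'   the remainder is the `none` state.
#' @param logr_gain_mean,logr_loss_mean Planted mean tumor logR for gained /
#'   lost segments.
#' @param signal_sd,baf_sd Gaussian noise SDs for the simulated array logR
#'   and BAF channels (set to 0 for noise-free signals).
#' @param missing_rate Probability that a genotype call is missing.
#' @param hazard_coef Log-hazard slope per log2-unit of the survival gene's
#'   (centered) normal expression; 0 means expression-independent survival.
#' @param survival_probe Probe whose expression drives the hazard; `NULL`
#'   uses the first probe of the expression matrix.
#' @param median_survival_months Baseline median survival used to set the
#'   exponential baseline rate.
#' @param censor_rate Probability that a case's survival time is
#'   independently right-censored.
#' @param seed Integer master seed; all generators derive fixed sub-streams
#'   from it, so identical configs give bit-identical outputs.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_cases = 50, n_controls = 50, n_expr_cases = 20,
#'                   n_array_cases = 10, n_snps = 30, n_genes = 5, seed = 1)
#' @export
sim_config <- function(n_cases = 1423L, n_controls = 1660L,
                       n_expr_cases = 100L, n_array_cases = 76L,
                       n_snps = 200L, n_genes = 20L,
                       maf_range = c(0.1, 0.5), window_bp = 20000L,
                       effect_table = NULL,
                       noise_sd = 0.5, tumor_shift = 0,
                       baseline_mean = 7, baseline_sd = 1,
                       somatic_rates = c(gain = 0.10, loss = 0.07,
                                         loh = 0.05, ai = 0.22),
                       logr_gain_mean = 0.5, logr_loss_mean = -0.5,
                       signal_sd = 0.1, baf_sd = 0.03,
                       missing_rate = 0,
                       hazard_coef = 0, survival_probe = NULL,
                       median_survival_months = 23.3,
                       censor_rate = 0.3, seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_expr_cases = as.integer(n_expr_cases),
    n_array_cases = as.integer(n_array_cases),
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    maf_range = as.numeric(maf_range), window_bp = as.integer(window_bp),
    effect_table = effect_table,
    noise_sd = noise_sd, tumor_shift = tumor_shift,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    somatic_rates = somatic_rates,
    logr_gain_mean = logr_gain_mean, logr_loss_mean = logr_loss_mean,
    signal_sd = signal_sd, baf_sd = baf_sd,
    missing_rate = missing_rate,
    hazard_coef = hazard_coef, survival_probe = survival_probe,
    median_survival_months = median_survival_months,
    censor_rate = censor_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 1, cfg$n_controls >= 0,
            cfg$n_snps >= 1, cfg$n_genes >= 1)
  if (cfg$n_expr_cases > cfg$n_cases)
    stop("n_expr_cases must not exceed n_cases")
  if (cfg$n_array_cases > cfg$n_expr_cases)
    stop("n_array_cases must not exceed n_expr_cases")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be two values in (0, 0.5], low <= high")
  if (cfg$window_bp < 0) stop("window_bp must be >= 0")
  for (p in c("censor_rate", "missing_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$signal_sd < 0 || cfg$baf_sd < 0)
    stop("noise/signal SDs must be nonnegative")
  sr <- somatic_rate_table(cfg$somatic_rates, paste0("g", seq_len(cfg$n_genes)))
  bad <- sr$gain + sr$loss + sr$loh + sr$ai
  if (any(c(sr$gain, sr$loss, sr$loh, sr$ai) < 0) || any(bad > 1 + 1e-12))
    stop("somatic_rates must be probabilities summing to <= 1 per gene")
  if (!is.null(cfg$effect_table)) {
    need <- c("snp_id", "beta_normal", "beta_tumor", "case_control_log_odds")
    if (!is.data.frame(cfg$effect_table) ||
        !all(need %in% names(cfg$effect_table)))
      stop("effect_table needs columns: ", paste(need, collapse = ", "))
  }
  if (!is.finite(cfg$hazard_coef)) stop("hazard_coef must be finite")
  invisible(cfg)
}

# Expand somatic_rates (vector or data.frame) to one row per gene symbol.
somatic_rate_table <- function(rates, gene_symbols) {
  states <- c("gain", "loss", "loh", "ai")
  if (is.data.frame(rates)) {
    stopifnot(all(c("gene_symbol", states) %in% names(rates)))
    out <- data.frame(gene_symbol = gene_symbols, gain = 0, loss = 0,
                      loh = 0, ai = 0, stringsAsFactors = FALSE)
    idx <- match(out$gene_symbol, rates$gene_symbol)
    for (s in states) out[[s]][!is.na(idx)] <- rates[[s]][idx[!is.na(idx)]]
    out
  } else {
    stopifnot(all(states %in% names(rates)))
    data.frame(gene_symbol = gene_symbols,
               gain = unname(rates["gain"]), loss = unname(rates["loss"]),
               loh = unname(rates["loh"]), ai = unname(rates["ai"]),
               stringsAsFactors = FALSE)
  }
}

# Deterministic per-component sub-streams off the master seed. Offsets are
# fixed so adding a component never reshuffles the others.
sim_seed <- function(cfg, component) {
  offsets <- c(annotation = 11L, genotypes = 23L, expression = 37L,
               somatic = 53L, survival = 71L)
  (cfg$seed + offsets[[component]]) %% .Machine$integer.max
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cases, "cases /", x$n_controls, "controls;",
      x$n_expr_cases, "expression cases;", x$n_array_cases, "array cases\n")
  cat("  ", x$n_snps, "SNPs,", x$n_genes, "genes, window", x$window_bp,
      "bp, seed", x$seed, "\n")
  invisible(x)
}
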