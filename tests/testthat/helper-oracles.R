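# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# all permutations of 1..n as an (n!) x n integer matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in 1:n)
    out[((i - 1) * nrow(p) + 1):(i * nrow(p)), ] <-
      cbind(i, matrix((1:n)[-i][p], nrow(p)))
  out
}

# exhaustive two-sided permutation p for Spearman's rho
perm_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y); n <- length(x)
  obs <- stats::cor(rx, ry)
  P <- all_perms(n)
  rho <- as.vector((matrix(ry[P], nrow(P)) - mean(ry)) %*% (rx - mean(rx))) /
    ((n - 1) * stats::sd(rx) * stats::sd(ry))
  mean(abs(rho) >= abs(obs) - 1e-12)
}

# brute-force interval scan for the SNP-to-gene window rule
brute_map <- function(snp_map, genes, window_bp) {
  out <- list()
  for (i in seq_len(nrow(snp_map))) {
    for (j in seq_len(nrow(genes))) {
      if (snp_map$chrom[i] != genes$chrom[j]) next
      p0 <- snp_map$pos[i] - 1L  # 0-based
      if (p0 >= genes$start[j] - window_bp && p0 < genes$end[j] + window_bp)
        out[[length(out) + 1]] <- data.frame(
          snp_id = snp_map$snp_id[i], gene_symbol = genes$gene_symbol[j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(snp_id = character(),
                                      gene_symbol = character()))
  do.call(rbind, out)
}

# straight-line re-statement of the gene-level aggregation rule
gene_call_oracle <- function(cn, ai, loh, min_fraction) {
  n <- length(cn)
  if (n == 0) return("none")
  if (sum(cn == "gain") / n >= min_fraction) return("gain")
  if (sum(cn == "loss") / n >= min_fraction) return("loss_or_loh")
  if (any(loh == "yes")) return("loss_or_loh")
  if (any(ai == "yes")) return("ai_only")
  "none"
}

# hand-computed two-group log-rank chi-squared via the standard O-E/V sums
logrank_hand <- function(time, event, group) {
  stopifnot(is.logical(group) || all(group %in% c(0, 1)))
  g <- as.integer(group)
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# 2x2 cross-product allelic/dosage odds ratio (dosage restricted to {0,1})
or_2x2 <- function(dosage, case) {
  a <- sum(case == 1 & dosage == 1); b <- sum(case == 1 & dosage == 0)
  c <- sum(case == 0 & dosage == 1); d <- sum(case == 0 & dosage == 0)
  (a * d) / (b * c)
}

# hand Benjamini-Hochberg
bh_hand <- function(p) {
  n <- length(p); o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n); out[o] <- pmin(1, q)
  out
}

# tiny planted-effect bundle used by several tests
flip_sim <- function(seed, beta_normal = -0.5, beta_tumor = 0, n = 100,
                     noise_sd = 0.5) {
  cfg <- sim_config(
    n_cases = n, n_controls = 0, n_expr_cases = n, n_array_cases = 1,
    n_snps = 1, n_genes = 1, maf_range = c(0.3, 0.3),
    effect_table = data.frame(snp_id = "snp00001",
                              beta_normal = beta_normal,
                              beta_tumor = beta_tumor,
                              case_control_log_odds = 0),
    noise_sd = noise_sd, seed = seed)
  ann <- simulate_annotation(cfg)
  geno <- simulate_genotypes(cfg, ann)
  expr <- simulate_expression(geno, ann, cfg)
  pairs <- data.frame(snp_id = "snp00001", probe_id = expr$probe_ids[1],
                      gene_symbol = "GENE001", stringsAsFactors = FALSE)
  list(cfg = cfg, ann = ann, geno = geno, expr = expr, pairs = pairs)
}
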