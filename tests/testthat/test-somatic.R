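mk_signal <- function(logr, baf, germ) {
  ns <- nrow(logr)
  structure(list(
    tumor_logr = logr, tumor_baf = baf, germline_genotype = germ,
    snp_ids = rownames(logr), case_ids = colnames(logr)),
    class = "array_signal")
}

one_case_signal <- function(logr, baf, germ) {
  n <- length(logr)
  ids <- paste0("s", seq_len(n))
  mk_signal(matrix(logr, n, 1, dimnames = list(ids, "c1")),
            matrix(baf, n, 1, dimnames = list(ids, "c1")),
            matrix(as.integer(germ), n, 1, dimnames = list(ids, "c1")))
}

test_that("per-SNP calling applies the threshold rules", {
  sig <- one_case_signal(logr = c(0, -0.5, 0.5, 0, 0),
                         baf = c(0.5, 0.95, 0.66, 0.75, 0.99),
                         germ = c(1, 1, 1, 1, 0))
  calls <- call_snp_states(sig)
  expect_equal(calls$cn_state, c("neutral", "loss", "gain", "neutral",
                                 "neutral"))
  # het, logR 0, BAF 0.5 -> nothing
  expect_equal(calls$ai_flag[1], "no"); expect_equal(calls$loh_flag[1], "no")
  # het, logR -0.5, BAF 0.95 -> loss + LOH (not AI: LOH wins)
  expect_equal(calls$loh_flag[2], "yes"); expect_equal(calls$ai_flag[2], "no")
  # het, logR +0.5, BAF 0.66 -> gain, no AI at the default 0.2 deviation
  expect_equal(calls$ai_flag[3], "no")
  # het, logR 0, BAF 0.75 -> AI, not LOH
  expect_equal(calls$ai_flag[4], "yes"); expect_equal(calls$loh_flag[4], "no")
  # homozygous germline -> allelic flags uninformative
  expect_equal(calls$ai_flag[5], "uninformative")
  expect_equal(calls$loh_flag[5], "uninformative")
})

test_that("BAF outside [0,1] is rejected", {
  sig <- one_case_signal(0, 1.2, 1)
  expect_error(call_snp_states(sig), "BAF")
})

test_that("gene aggregation applies precedence and AI annotation", {
  mapping <- data.frame(snp_id = c("s1", "s2", "s3"), gene_symbol = "G1")
  calls <- data.frame(
    snp_id = c("s1", "s2", "s3"), case_id = "c1",
    cn_state = c("gain", "gain", "neutral"),
    ai_flag = c("no", "no", "yes"), loh_flag = c("no", "no", "no"))
  g <- call_gene_alterations(calls, mapping)
  expect_equal(g$category, "gain")
  expect_true(g$with_ai)

  calls2 <- calls; calls2$cn_state <- "neutral"
  calls2$ai_flag <- c("no", "yes", "no")
  g2 <- call_gene_alterations(calls2, mapping)
  expect_equal(g2$category, "ai_only")
  expect_false(g2$with_ai)
})

test_that("gene aggregation matches an independent rule re-statement", {
  set.seed(61)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    mapping <- data.frame(snp_id = paste0("s", 1:n), gene_symbol = "G")
    het <- sample(c(TRUE, FALSE), n, TRUE)
    calls <- data.frame(
      snp_id = paste0("s", 1:n), case_id = "c1",
      cn_state = sample(c("gain", "loss", "neutral"), n, TRUE),
      ai_flag = ifelse(het, sample(c("yes", "no"), n, TRUE),
                       "uninformative"),
      loh_flag = ifelse(het, sample(c("yes", "no"), n, TRUE),
                        "uninformative"))
    mf <- sample(c(0.3, 0.5, 1), 1)
    got <- call_gene_alterations(calls, mapping, mf)
    expect_equal(got$category,
                 gene_call_oracle(calls$cn_state, calls$ai_flag,
                                  calls$loh_flag, mf))
  }
})

test_that("raising the gain threshold never adds gain calls", {
  set.seed(62)
  sig <- one_case_signal(rnorm(50, 0.2, 0.3),
                         pmin(1, pmax(0, rnorm(50, 0.5, 0.2))),
                         sample(0:2, 50, TRUE))
  prev <- Inf
  for (thr in c(0.1, 0.2, 0.4)) {
    ngain <- sum(call_snp_states(
      sig, somatic_thresholds(logr_gain = thr))$cn_state == "gain")
    expect_lte(ngain, prev)
    prev <- ngain
  }
})

test_that("expression abnormality thresholds mean fold change per gene", {
  normal <- matrix(0, 2, 3, dimnames = list(c("p1", "p2"),
                                            c("c1", "c2", "c3")))
  tumor <- matrix(c(1.5, 1.5, 0, 0, -1.2, -0.8), 2, 3,
                  dimnames = dimnames(normal))
  pe <- structure(list(normal_log2 = normal, tumor_log2 = tumor,
                       probe_ids = rownames(normal),
                       case_ids = colnames(normal)),
                  class = "paired_expression")
  pm <- data.frame(probe_id = c("p1", "p2"), gene_symbol = "G1")
  ab <- expression_abnormality(pe, pm, fc_threshold = 1)
  expect_equal(ab$status, c("over", "normal", "under"))
  expect_equal(ab$log2fc, c(1.5, 0, -1))
})

test_that("frequency table arithmetic and conservation identities hold", {
  gc <- data.frame(
    gene_symbol = "G1",
    case_id = paste0("c", 1:76),
    category = rep(c("gain", "ai_only", "loss_or_loh", "none"),
                   c(20, 8, 5, 43)),
    with_ai = FALSE)
  ab <- data.frame(gene_symbol = "G1", case_id = paste0("e", 1:100),
                   log2fc = 0,
                   status = rep(c("over", "under", "normal"),
                                c(33, 10, 57)))
  ft <- frequency_table(gc, ab)
  expect_equal(ft$freq_gain, 20 / 76)
  expect_equal(ft$freq_total, 33 / 76)  # 33 of 76 altered -> 0.434...
  expect_equal(ft$freq_over, 0.33)
  expect_equal(ft$freq_abnormal, ft$freq_over + ft$freq_under)
  expect_equal(ft$freq_total,
               ft$freq_ai_only + ft$freq_gain + ft$freq_loss_loh)
  expect_equal(ft$n_expr, 100)
  expect_equal(ft$n_array, 76)
})

test_that("noise-free simulation round-trips latent states through the caller", {
  cfg <- sim_config(n_cases = 30, n_controls = 0, n_expr_cases = 30,
                    n_array_cases = 30, n_snps = 160, n_genes = 4,
                    maf_range = c(0.5, 0.5), signal_sd = 0, baf_sd = 0,
                    missing_rate = 0,
                    somatic_rates = c(gain = 0.2, loss = 0.2, loh = 0.2,
                                      ai = 0.2), seed = 63)
  ann <- simulate_annotation(cfg)
  geno <- simulate_genotypes(cfg, ann)
  sig <- simulate_somatic(geno, ann, cfg)
  mapping <- map_snps_to_genes(geno$snp_map, ann, cfg$window_bp)
  gc <- call_gene_alterations(call_snp_states(sig), mapping)
  expected <- c(gain = "gain", loss = "loss_or_loh", loh = "loss_or_loh",
                ai = "ai_only", none = "none")
  # allelic-only states need a het SNP in the window to be observable
  het_informative <- vapply(seq_len(nrow(gc)), function(i) {
    snps <- mapping$snp_id[mapping$gene_symbol == gc$gene_symbol[i]]
    any(sig$germline_genotype[snps, gc$case_id[i]] == 1L, na.rm = TRUE)
  }, logical(1))
  latent <- sig$latent_states[cbind(gc$gene_symbol, gc$case_id)]
  check <- het_informative | latent %in% c("gain", "loss", "none")
  expect_gt(mean(het_informative), 0.95)
  expect_equal(gc$category[check], unname(expected[latent[check]]))
})
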