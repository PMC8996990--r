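test_that("window mapping honors the half-open boundary exactly", {
  genes <- data.frame(gene_symbol = "G1", chrom = "chr1",
                      start = 1000L, end = 2000L)
  snp <- function(pos) data.frame(snp_id = paste0("s", pos), chrom = "chr1",
                                  pos = pos)
  mapped <- function(pos)
    nrow(map_snps_to_genes(snp(pos), genes, 20000L)) == 1L
  expect_true(mapped(21999L))   # 21998 < 22000
  expect_true(mapped(22000L))   # 21999 < 22000, last base in
  expect_false(mapped(22001L))  # 22000 is out
  # left boundary with a narrow window: P - 1 >= start - w  <=>  P >= 901
  narrow <- function(pos)
    nrow(map_snps_to_genes(snp(pos), genes, 100L)) == 1L
  expect_true(narrow(901L))
  expect_false(narrow(900L))
})

test_that("window mapping equals a brute-force interval scan", {
  set.seed(31)
  for (rep in 1:5) {
    genes <- data.frame(
      gene_symbol = paste0("G", 1:4), chrom = "chr1",
      start = sort(sample.int(50000L, 4)))
    genes$end <- genes$start + sample(500:5000, 4)
    snp_map <- data.frame(snp_id = paste0("s", 1:30), chrom = "chr1",
                          pos = sample.int(80000L, 30))
    w <- sample(c(0L, 100L, 2000L), 1)
    got <- map_snps_to_genes(snp_map, genes, w)
    want <- brute_map(snp_map, genes, w)
    key <- function(d) sort(paste(d$snp_id, d$gene_symbol))
    expect_identical(key(got), key(want))
  }
})

test_that("enlarging the window never removes a SNP-gene link", {
  set.seed(32)
  genes <- data.frame(gene_symbol = paste0("G", 1:3), chrom = "chr1",
                      start = c(1000L, 30000L, 90000L))
  genes$end <- genes$start + 2000L
  snp_map <- data.frame(snp_id = paste0("s", 1:50), chrom = "chr1",
                        pos = sample.int(120000L, 50))
  prev <- character(0)
  for (w in c(0L, 500L, 5000L, 20000L)) {
    cur <- with(map_snps_to_genes(snp_map, genes, w),
                paste(snp_id, gene_symbol))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("chromosome name mismatch is reported", {
  genes <- data.frame(gene_symbol = "G1", chrom = "chr1",
                      start = 0L, end = 100L)
  snp_map <- data.frame(snp_id = "s1", chrom = "1", pos = 50L)
  expect_error(map_snps_to_genes(snp_map, genes, 0L), "chromosome")
})

make_screen_fixture <- function(dosage, case, seed = 1) {
  n <- length(dosage)
  ids <- sprintf("s%03d", seq_len(n))
  geno <- structure(list(
    dosages = matrix(as.integer(dosage), 1, n,
                     dimnames = list("snpA", ids)),
    sample_ids = ids, snp_ids = "snpA",
    snp_map = data.frame(snp_id = "snpA", chrom = "chr1", pos = 1L,
                         ref = "A", alt = "G")), class = "genotype_matrix")
  ph <- data.frame(sample_id = ids,
                   status = ifelse(case == 1, "case", "control"),
                   age = 50L, gender = "male", stringsAsFactors = FALSE)
  list(geno = geno, ph = ph)
}

test_that("logistic OR equals the 2x2 cross-product ratio on binary dosage", {
  # constant covariates are aliased out, so the fit is the unadjusted model
  dosage <- rep(c(1, 0, 1, 0), c(30, 70, 15, 85))
  case <- rep(c(1, 1, 0, 0), c(30, 70, 15, 85))
  f <- make_screen_fixture(dosage, case)
  res <- association_screen(f$geno, f$ph)
  expect_false(res$skipped)
  expect_lt(abs(res$or_point - or_2x2(dosage, case)), 1e-6)
  expect_true(res$ci_low <= res$or_point && res$or_point <= res$ci_high)
  expect_equal(res$or_point, exp(res$beta))
})

test_that("null dosage is non-significant and constant dosage is skipped", {
  set.seed(33)
  dosage <- sample(0:2, 400, TRUE)
  case <- rep(c(1, 0), 200)
  f <- make_screen_fixture(dosage, case)
  res <- association_screen(f$geno, f$ph)
  expect_false(res$significant)
  expect_true(res$wald_agree)

  f2 <- make_screen_fixture(rep(1, 400), case)
  res2 <- association_screen(f2$geno, f2$ph)
  expect_true(res2$skipped)
  expect_match(res2$skip_reason, "constant")
})

test_that("Wald CI covers a planted odds ratio of 2", {
  covered <- vapply(1:30, function(i) {
    cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_expr_cases = 1,
                      n_array_cases = 1, n_snps = 1, n_genes = 1,
                      maf_range = c(0.3, 0.3),
                      effect_table = data.frame(
                        snp_id = "snp00001", beta_normal = 0,
                        beta_tumor = 0, case_control_log_odds = log(2)),
                      seed = 300 + i)
    g <- simulate_genotypes(cfg)
    ph <- data.frame(sample_id = g$sample_ids,
                     status = ifelse(grepl("^case", g$sample_ids),
                                     "case", "control"),
                     age = 50L, gender = "male")
    r <- association_screen(g, ph)
    r$ci_low <= 2 && 2 <= r$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("test-set join matches a brute-force triple join", {
  mapping <- data.frame(snp_id = c("s1", "s1", "s2", "s3"),
                        gene_symbol = c("G1", "G2", "G2", "G3"))
  screen <- data.frame(snp_id = c("s1", "s2", "s3"),
                       significant = c(TRUE, TRUE, FALSE))
  pm <- data.frame(probe_id = c("p1a", "p1b", "p2", "p3"),
                   gene_symbol = c("G1", "G1", "G2", "G3"))
  got <- select_test_set(mapping, screen, pm)
  # s1 -> G1 (2 probes) + G2 (1 probe); s2 -> G2; s3 not significant
  expect_equal(nrow(got), 4)
  expect_setequal(paste(got$snp_id, got$probe_id),
                  c("s1 p1a", "s1 p1b", "s1 p2", "s2 p2"))

  # randomized instance vs explicit nested-loop join
  set.seed(34)
  mapping <- unique(data.frame(
    snp_id = sample(paste0("s", 1:8), 20, TRUE),
    gene_symbol = sample(paste0("G", 1:5), 20, TRUE)))
  screen <- data.frame(snp_id = paste0("s", 1:8),
                       significant = sample(c(TRUE, FALSE), 8, TRUE))
  pm <- unique(data.frame(probe_id = paste0("p", 1:10),
                          gene_symbol = sample(paste0("G", 1:5), 10, TRUE)))
  got <- select_test_set(mapping, screen, pm)
  want <- character(0)
  for (i in seq_len(nrow(mapping)))
    for (j in seq_len(nrow(pm)))
      if (mapping$gene_symbol[i] == pm$gene_symbol[j] &&
          screen$significant[screen$snp_id == mapping$snp_id[i]])
        want <- c(want, paste(mapping$snp_id[i], pm$probe_id[j],
                              pm$gene_symbol[j]))
  expect_setequal(paste(got$snp_id, got$probe_id, got$gene_symbol),
                  unique(want))
})

test_that("empty significant set yields an empty test set with a warning", {
  mapping <- data.frame(snp_id = "s1", gene_symbol = "G1")
  screen <- data.frame(snp_id = "s1", significant = FALSE)
  pm <- data.frame(probe_id = "p1", gene_symbol = "G1")
  expect_warning(got <- select_test_set(mapping, screen, pm),
                 "no screen-significant")
  expect_equal(nrow(got), 0)
})
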