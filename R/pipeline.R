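#' Pipeline run configuration
#'
#' @param genotypes_tsv,expression_normal,expression_tumor,phenotypes,array_signal,genes_bed,pathways_gmt,probe_map
#'   Input file paths (see [write_input_bundle()] for the formats);
#'   `array_signal` may be `NULL` to skip the somatic stage.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param window_bp Flanking window for SNP-to-gene mapping.
#' @param alpha Nominal significance level used by the screen, the scans
#'   and the intersection.
#' @param thresholds [somatic_thresholds()] list.
#' @param min_fraction Gene-level CN aggregation fraction.
#' @param fc_threshold Expression over/under threshold (log2).
#' @param min_n Minimum complete pairs per eQTL test.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(genotypes_tsv, expression_normal, expression_tumor,
                       phenotypes, array_signal = NULL, genes_bed,
                       pathways_gmt, probe_map, out_dir,
                       window_bp = 20000L, alpha = 0.05,
                       thresholds = somatic_thresholds(),
                       min_fraction = 0.5, fc_threshold = 1,
                       min_n = 3L, seed = 1L) {
  cfg <- list(genotypes_tsv = genotypes_tsv,
              expression_normal = expression_normal,
              expression_tumor = expression_tumor,
              phenotypes = phenotypes, array_signal = array_signal,
              genes_bed = genes_bed, pathways_gmt = pathways_gmt,
              probe_map = probe_map, out_dir = out_dir,
              window_bp = as.integer(window_bp), alpha = alpha,
              thresholds = thresholds, min_fraction = min_fraction,
              fc_threshold = fc_threshold, min_n = as.integer(min_n),
              seed = as.integer(seed))
  inputs <- c("genotypes_tsv", "expression_normal", "expression_tumor",
              "phenotypes", "genes_bed", "pathways_gmt", "probe_map")
  for (f in inputs)
    if (!file.exists(cfg[[f]])) stop("input file missing: ", cfg[[f]])
  if (!is.null(cfg$array_signal) && !file.exists(cfg$array_signal))
    stop("input file missing: ", cfg$array_signal)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param base_dir Directory relative paths are resolved against (defaults
#'   to the YAML file's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^/", p)) file.path(base_dir, p) else p
  }
  for (f in c("genotypes_tsv", "expression_normal", "expression_tumor",
              "phenotypes", "array_signal", "genes_bed", "pathways_gmt",
              "probe_map", "out_dir"))
    y[[f]] <- resolve(y[[f]])
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(y$thresholds))
    args$thresholds <- do.call(somatic_thresholds, y$thresholds)
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_msg <- function(...) message("[dualqtl] ", ...)

#' Run the integrated pipeline
#'
#' Executes locus selection (window mapping + association screen + test
#' set), the classical and modified eQTL scans, the shared-pair
#' intersection with direction classification, the somatic segment stage
#' (when array signals are provided) and the downstream characterization
#' (paired DEG with BH FDR; median-split log-rank survival for shared
#' genes). Every stage writes a TSV under `config$out_dir`, and a
#' `manifest.json` records the config hash, seed and per-stage row counts.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list()
  stage <- function(name, expr) {
    stage_msg("stage ", name, " ...")
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stage_msg("stage ", name, " done in ",
              sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  geno <- stage("read_inputs", {
    g <- read_genotypes_tsv(config$genotypes_tsv)
    g
  })
  expr <- read_expression_pair(config$expression_normal,
                               config$expression_tumor)
  pheno <- read_phenotypes_tsv(config$phenotypes)
  ann <- read_gene_annotation(config$genes_bed, config$pathways_gmt,
                              config$probe_map)
  pm <- probe_map(ann)

  mapping <- stage("locus_selection", {
    map_snps_to_genes(geno$snp_map, ann, config$window_bp)
  })
  screen <- stage("association_screen",
                  association_screen(geno, pheno, config$alpha))
  pairs <- stage("select_test_set", select_test_set(mapping, screen, pm))
  counts$mapping <- nrow(mapping); counts$screen_significant <-
    sum(screen$significant, na.rm = TRUE); counts$pairs <- nrow(pairs)

  empty <- nrow(pairs) == 0L
  if (empty) warning("empty test set; downstream eQTL tables will be empty")

  classical <- stage("classical_scan",
                     classical_scan(geno, expr, pairs, config$min_n))
  modified <- stage("modified_scan",
                    modified_scan(geno, expr, pairs, config$min_n))
  shared <- stage("shared_eqtl",
                  intersect_pairs(classical, modified, config$alpha))
  gene_sets <- shared_genes(classical, modified, shared, config$alpha)
  counts$classical_significant <-
    sum(!is.na(classical$p) & classical$p < config$alpha)
  counts$modified_significant <-
    sum(!is.na(modified$p) & modified$p < config$alpha)
  counts$shared_pairs <- nrow(shared)
  counts$shared_genes <- length(gene_sets$genes_all)

  somatic_res <- NULL
  if (!is.null(config$array_signal)) {
    somatic_res <- stage("somatic_segments", {
      sig <- read_array_signal_tsv(config$array_signal)
      sm <- geno$snp_map[geno$snp_map$snp_id %in% sig$snp_ids, ]
      arr_map <- map_snps_to_genes(sm, ann, config$window_bp)
      snp_calls <- call_snp_states(sig, config$thresholds)
      gene_calls <- call_gene_alterations(snp_calls, arr_map,
                                          config$min_fraction)
      ab <- expression_abnormality(expr, pm, config$fc_threshold)
      list(snp_calls = snp_calls, gene_calls = gene_calls,
           abnormality = ab,
           frequency = frequency_table(gene_calls, ab))
    })
    counts$gene_alteration_calls <- nrow(somatic_res$gene_calls)
  }

  deg <- stage("paired_deg", paired_deg(expr, pm))
  surv <- stage("survival_screen", {
    if (length(gene_sets$genes_all))
      survival_screen(pheno, expr, pm, gene_sets$genes_all)
    else data.frame()
  })
  counts$deg_fdr_significant <- sum(deg$fdr_q < 0.05, na.rm = TRUE)

  write_tsv(screen, out("screen.tsv"))
  write_tsv(pairs, out("pairs.tsv"))
  write_tsv(classical, out("eqtl_classical.tsv"))
  write_tsv(modified, out("eqtl_modified.tsv"))
  write_tsv(shared, out("shared_pairs.tsv"))
  write_tsv(data.frame(
    gene_symbol = gene_sets$genes_all,
    set = ifelse(gene_sets$genes_all %in% gene_sets$genes_same_pairs,
                 "same_pairs", "different_pairs")), out("shared_genes.tsv"))
  if (!is.null(somatic_res)) {
    write_tsv(somatic_res$gene_calls, out("gene_alterations.tsv"))
    write_tsv(somatic_res$frequency, out("frequency_table.tsv"))
  }
  write_tsv(deg, out("deg.tsv"))
  if (nrow(surv)) write_tsv(surv, out("survival.tsv"))

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   alpha = config$alpha, row_counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(screen = screen, pairs = pairs, classical = classical,
                 modified = modified, shared_pairs = shared,
                 shared_genes = gene_sets, somatic = somatic_res, deg = deg,
                 survival = surv, manifest = manifest))
}

# md5 of the serialized config (paths included), via tools::md5sum
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), file = tmp)
  unname(tools::md5sum(tmp))
}
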