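#' @name dualqtl-io
#' @title Readers and writers for the pipeline's plain-text formats
#'
#' @description Genotypes travel as a dosage TSV (snp metadata columns +
#' one column per sample) or as VCF with GT genotypes; expression layers
#' as probes-by-cases TSVs; phenotypes, array signals and the probe map as
#' TSVs; gene annotation as BED (0-based half-open) plus a GMT pathway
#' file. All writers emit tab-separated text with a header row.
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)

#' @rdname dualqtl-io
#' @param genotypes A `genotype_matrix`.
#' @param path Output or input file path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$snp_map[, c("snp_id", "chrom", "pos", "ref", "alt")],
              as.data.frame(genotypes$dosages, check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname dualqtl-io
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_tsv(path)
  meta <- c("snp_id", "chrom", "pos", "ref", "alt")
  stopifnot(all(meta %in% names(df)))
  samples <- setdiff(names(df), meta)
  dos <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(dos) <- "integer"
  if (any(!is.na(dos) & !(dos %in% 0:2))) stop("dosages must be 0/1/2/NA")
  rownames(dos) <- df$snp_id
  structure(list(dosages = dos, sample_ids = samples, snp_ids = df$snp_id,
                 snp_map = df[, meta]),
            class = "genotype_matrix")
}

#' @rdname dualqtl-io
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=dualqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$sample_ids),
                     collapse = "\t")),
             con)
  sm <- genotypes$snp_map
  for (i in seq_along(genotypes$snp_ids)) {
    g <- genotypes$dosages[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(sm$chrom[i], sm$pos[i], sm$snp_id[i], sm$ref[i],
                       sm$alt[i], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname dualqtl-io
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  structure(list(dosages = dos, sample_ids = colnames(gt),
                 snp_ids = fix$ID,
                 snp_map = data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                                      pos = as.integer(fix$POS),
                                      ref = fix$REF, alt = fix$ALT,
                                      stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @rdname dualqtl-io
#' @param mat A probes-by-cases numeric matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname dualqtl-io
#' @param normal_path,tumor_path Paths of the two expression layers; probe
#'   and case axes must match.
#' @export
read_expression_pair <- function(normal_path, tumor_path) {
  rd <- function(p) {
    df <- read_tsv(p)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  normal <- rd(normal_path); tumor <- rd(tumor_path)
  if (!identical(dimnames(normal), dimnames(tumor)))
    stop("normal and tumor layers must share probe and case axes")
  if (any(!is.finite(normal)) || any(!is.finite(tumor)))
    stop("expression values must be finite")
  structure(list(normal_log2 = normal, tumor_log2 = tumor,
                 probe_ids = rownames(normal), case_ids = colnames(normal)),
            class = "paired_expression")
}

#' @rdname dualqtl-io
#' @param phenotypes A `phenotype_table`.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) write_tsv(phenotypes, path)

#' @rdname dualqtl-io
#' @export
read_phenotypes_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "status", "age", "gender")
  stopifnot(all(need %in% names(df)))
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname dualqtl-io
#' @param signal An `array_signal`.
#' @export
write_array_signal_tsv <- function(signal, path) {
  ns <- length(signal$snp_ids)
  df <- data.frame(
    snp_id = rep(signal$snp_ids, length(signal$case_ids)),
    case_id = rep(signal$case_ids, each = ns),
    logr = as.vector(signal$tumor_logr),
    baf = as.vector(signal$tumor_baf),
    germline_gt = as.vector(signal$germline_genotype),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname dualqtl-io
#' @export
read_array_signal_tsv <- function(path) {
  df <- read_tsv(path)
  snps <- unique(df$snp_id); cases <- unique(df$case_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(snps), length(cases),
                dimnames = list(snps, cases))
    m[cbind(match(df$snp_id, snps), match(df$case_id, cases))] <- df[[col]]
    m
  }
  germ <- shape("germline_gt"); storage.mode(germ) <- "integer"
  structure(list(tumor_logr = shape("logr"), tumor_baf = shape("baf"),
                 germline_genotype = germ, snp_ids = snps, case_ids = cases),
            class = "array_signal")
}

#' @rdname dualqtl-io
#' @param annotation A gene annotation table.
#' @export
write_gene_bed <- function(annotation, path) {
  df <- data.frame(annotation$chrom, annotation$start, annotation$end,
                   annotation$gene_symbol)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname dualqtl-io
#' @export
write_gmt <- function(annotation, path) {
  paths <- strsplit(annotation$pathways, ",", fixed = TRUE)
  all_paths <- sort(unique(unlist(paths)))
  lines <- vapply(all_paths, function(p) {
    genes <- annotation$gene_symbol[vapply(paths, function(x) p %in% x,
                                           logical(1))]
    paste(c(p, "na", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname dualqtl-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(x) x[-(1:2)]),
           vapply(parts, `[`, character(1), 1))
}

#' @rdname dualqtl-io
#' @param bed_path,gmt_path,probe_map_path Annotation component files.
#' @export
read_gene_annotation <- function(bed_path, gmt_path, probe_map_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "gene_symbol"))
  gmt <- read_gmt(gmt_path)
  pm <- read_tsv(probe_map_path)
  pathways <- vapply(bed$gene_symbol, function(g) {
    hit <- names(gmt)[vapply(gmt, function(x) g %in% x, logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  probes <- vapply(bed$gene_symbol, function(g)
    paste(pm$probe_id[pm$gene_symbol == g], collapse = ","), character(1))
  ann <- data.frame(gene_symbol = bed$gene_symbol, chrom = bed$chrom,
                    start = bed$start, end = bed$end, pathways = pathways,
                    probes = probes, stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write the full synthetic input bundle
#'
#' Runs every generator off one configuration and writes the file set the
#' pipeline consumes: genotypes (VCF + dosage TSV), both expression layers,
#' phenotypes, array signals, gene BED, pathway GMT and probe map.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of file paths plus the in-memory
#'   objects (`$objects`).
#' @export
write_input_bundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- simulate_annotation(config)
  geno <- simulate_genotypes(config, ann)
  expr <- simulate_expression(geno, ann, config)
  somatic <- simulate_somatic(geno, ann, config)
  pheno <- simulate_survival(expr, config)
  p <- function(f) file.path(dir, f)
  paths <- list(
    genotypes_vcf = write_genotypes_vcf(geno, p("genotypes.vcf")),
    genotypes_tsv = write_genotypes_tsv(geno, p("genotypes.tsv")),
    expression_normal = write_expression_tsv(expr$normal_log2,
                                             p("expression_normal.tsv")),
    expression_tumor = write_expression_tsv(expr$tumor_log2,
                                            p("expression_tumor.tsv")),
    phenotypes = write_phenotypes_tsv(pheno, p("phenotypes.tsv")),
    array_signal = write_array_signal_tsv(somatic, p("array_signal.tsv")),
    genes_bed = write_gene_bed(ann, p("genes.bed")),
    pathways_gmt = write_gmt(ann, p("pathways.gmt")),
    probe_map = write_tsv(probe_map(ann), p("probe_map.tsv")))
  paths$objects <- list(annotation = ann, genotypes = geno,
                        expression = expr, somatic = somatic,
                        phenotypes = pheno)
  invisible(paths)
}
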