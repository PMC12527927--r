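#' Read and write QTL summary statistics
#'
#' Tab-separated dialect with the fixed header
#' `SNP CHR POS EA OA GENE GENE_CHR GENE_TSS BETA SE P`, mapped to the
#' internal record columns `snp_id, chrom, pos, ea, oa, gene_id, gene_chrom,
#' gene_tss, beta, se, p`.
#'
#' @param path file path.
#' @name sumstats_io
NULL

.SUMSTAT_HEADER <- c("SNP", "CHR", "POS", "EA", "OA", "GENE", "GENE_CHR",
                     "GENE_TSS", "BETA", "SE", "P")
.SUMSTAT_INTERNAL <- c("snp_id", "chrom", "pos", "ea", "oa", "gene_id",
                       "gene_chrom", "gene_tss", "beta", "se", "p")

#' @rdname sumstats_io
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!identical(strsplit(readLines(path, n = 1), "\t")[[1]], .SUMSTAT_HEADER))
    stop(sprintf("unexpected summary-statistic header; expected: %s",
                 paste(.SUMSTAT_HEADER, collapse = " ")), call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character",
                                        GENE_CHR = "character"))
  names(x) <- .SUMSTAT_INTERNAL
  if (any(x$se <= 0)) stop("standard errors must be positive", call. = FALSE)
  if (any(x$p <= 0 | x$p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  x
}

#' @rdname sumstats_io
#' @param records QTL record data.frame.
#' @export
write_sumstats <- function(records, path) {
  out <- records[, .SUMSTAT_INTERNAL]
  names(out) <- .SUMSTAT_HEADER
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype dosages as TSV
#'
#' The dosage matrix is samples x SNPs with an `IID` first column; SNP
#' metadata (`SNP CHR POS EA OA`) travels in a sidecar TSV.
#'
#' @param path dosage TSV path.
#' @param meta_path sidecar SNP metadata TSV path.
#' @name dosage_io
NULL

#' @rdname dosage_io
#' @export
read_dosages <- function(path, meta_path) {
  for (p in c(path, meta_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = c(CHR = "character"))
  names(meta) <- c("snp_id", "chrom", "pos", "ea", "oa")[seq_along(names(meta))]
  ids <- d$IID
  D <- as.matrix(d[, setdiff(names(d), "IID"), drop = FALSE])
  rownames(D) <- ids
  if (!identical(colnames(D), meta$snp_id))
    stop("dosage columns do not match the SNP metadata sidecar", call. = FALSE)
  structure(list(dosages = D, snp_meta = meta, sample_ids = ids),
            class = "genotype_matrix")
}

#' @rdname dosage_io
#' @param geno a `genotype_matrix`.
#' @export
write_dosages <- function(geno, path, meta_path) {
  d <- data.frame(IID = geno$sample_ids, geno$dosages, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- geno$snp_meta[, c("snp_id", "chrom", "pos", "ea", "oa")]
  names(meta) <- c("SNP", "CHR", "POS", "EA", "OA")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS FORMAT field
#'
#' Uses the `vcfR` package. Missing dosages stay `NA` (mean-imputed later at
#' score construction).
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package `vcfR` is required to read VCF input", call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fx <- vcfR::getFIX(v)
  D <- t(ds)
  colnames(D) <- fx[, "ID"]
  meta <- data.frame(snp_id = fx[, "ID"], chrom = as.character(fx[, "CHROM"]),
                     pos = as.numeric(fx[, "POS"]), ea = fx[, "ALT"],
                     oa = fx[, "REF"], stringsAsFactors = FALSE)
  structure(list(dosages = D, snp_meta = meta, sample_ids = rownames(D)),
            class = "genotype_matrix")
}

#' Read and write phenotype/covariate tables
#'
#' TSV with columns `IID, STATUS (0/1), SEX, COHORT, PC1..PCk`.
#' @param path file path.
#' @name pheno_io
NULL

#' @rdname pheno_io
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("IID", "STATUS") %in% names(x)))
    stop("phenotype table must contain IID and STATUS columns", call. = FALSE)
  if (!all(x$STATUS %in% 0:1)) stop("STATUS must be 0/1", call. = FALSE)
  x
}

#' @rdname pheno_io
#' @param pheno phenotype data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write score definitions as a locus JSON manifest
#'
#' gene -> clumps -> member SNP ids, positions, marginal betas and
#' LD-adjusted weights.
#'
#' @param defs a `gate_definitions` object.
#' @param path output path.
#' @export
write_locus_json <- function(defs, path) {
  stopifnot(inherits(defs, "gate_definitions"))
  out <- lapply(defs, function(d) {
    loci <- lapply(split(d$snps, d$snps$locus_id), function(s)
      list(snp_id = s$snp_id, chrom = unique(s$chrom), pos = s$pos,
           marginal_beta = s$beta, adjusted_weight = s$weight))
    list(gene_id = d$gene_id, score_type = d$score_type,
         n_trans_loci = d$n_trans_loci, loci = loci)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a score matrix as TSV (IID plus one column per score)
#' @param scores a `score_matrix`.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_matrix"))
  d <- data.frame(IID = rownames(scores$values), scores$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
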