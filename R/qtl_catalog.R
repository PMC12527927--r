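#' Classify QTL records as cis or trans
#'
#' A record is trans if the SNP lies on a different chromosome from its target
#' gene, or at least `cis_window` base pairs from the gene's transcription
#' start site; otherwise cis. The 5 Mb default follows the convention of
#' whole-blood eQTL catalogues.
#'
#' @param records QTL record data.frame (see [reference_summary_stats()] for
#'   the column contract).
#' @param cis_window distance threshold in bp.
#' @return character vector, one of `"cis"`/`"trans"` per record.
#' @export
classify_cis_trans <- function(records, cis_window = 5e6) {
  if (any(is.na(records$gene_tss)) || any(is.na(records$gene_chrom)))
    stop("records with missing gene TSS/chromosome cannot be classified",
         call. = FALSE)
  ifelse(as.character(records$chrom) != as.character(records$gene_chrom) |
           abs(records$pos - records$gene_tss) >= cis_window,
         "trans", "cis")
}

#' Remove trans-QTLs inside the HLA region
#'
#' The HLA region (chromosome 6, 25-34 Mb) is a trans-QTL hotspot whose
#' strong direct disease effects would confound aggregated trans-scores;
#' records inside it are excluded from GATE input and routed to a separate
#' HLA-specific score set. Endpoints are inclusive, coordinates 1-based.
#'
#' @param records QTL record data.frame.
#' @param region list with `chrom`, `start`, `end` (defaults to chr6 25-34 Mb).
#' @return list with elements `kept` (records outside the region) and `hla`
#'   (records inside it).
#' @export
mask_hla <- function(records, region = list(chrom = "6", start = 25e6, end = 34e6)) {
  chrom <- sub("^chr", "", as.character(records$chrom))
  inside <- chrom == sub("^chr", "", as.character(region$chrom)) &
    records$pos >= region$start & records$pos <= region$end
  list(kept = records[!inside, , drop = FALSE],
       hla = records[inside, , drop = FALSE])
}

#' Select QTL records for score construction
#'
#' Trans records are retained below the trans p-value threshold. A cis score
#' is defined for a gene only when at least one cis SNP reaches `cis_p`
#' (default 1e-6); for such genes the cis records passing `cis_p` are kept.
#'
#' @param records QTL record data.frame.
#' @param trans_p genome-wide trans inclusion threshold (default 5e-8).
#' @param cis_p cis-score qualification threshold (default 1e-6).
#' @param cis_window passed to [classify_cis_trans()].
#' @return list with data.frames `trans` and `cis`.
#' @export
select_qtls <- function(records, trans_p = 5e-8, cis_p = 1e-6, cis_window = 5e6) {
  if (nrow(records) == 0)
    return(list(trans = records, cis = records))
  lab <- classify_cis_trans(records, cis_window)
  trans <- records[lab == "trans" & records$p < trans_p, , drop = FALSE]
  cis <- records[lab == "cis" & records$p < cis_p, , drop = FALSE]
  list(trans = trans, cis = cis)
}

#' Clump QTL records by genomic proximity
#'
#' Within each gene and chromosome, SNPs are merged into one locus when they
#' can be chained by steps of at most `window` bp (single-linkage/transitive
#' closure: in one dimension this is equivalent to splitting the sorted
#' positions wherever the gap exceeds the window). The partition is exhaustive
#' and disjoint.
#'
#' @param records QTL record data.frame for one or more genes.
#' @param window chaining distance in bp (default 200 kb).
#' @return `records` with an added `locus_id` column
#'   (`<gene>:<chrom>:<serial>`), rows ordered by gene, chromosome, position.
#' @export
clump_qtls <- function(records, window = 2e5) {
  if (nrow(records) == 0) {
    records$locus_id <- character(0)
    return(records)
  }
  ord <- order(records$gene_id, records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$gene_id, records$chrom, sep = ":")
  locus <- character(nrow(records))
  for (k in unique(key)) {
    i <- which(key == k)
    gaps <- c(0, diff(records$pos[i]))
    serial <- cumsum(gaps > window) + 1L
    locus[i] <- sprintf("%s:%d", k, serial)
  }
  records$locus_id <- locus
  rownames(records) <- NULL
  records
}

#' LD-adjust marginal effect sizes within a locus
#'
#' Converts marginal per-SNP effects into approximately joint effects by
#' solving `(R + ridge * I) w = beta` on the standardized scale, where `R` is
#' the SNP correlation matrix in a reference panel. With `ridge = 0` and an
#' invertible `R` this reproduces the multiple-regression coefficients in the
#' reference population; a small positive ridge stabilizes near-collinear
#' clumps while leaving independent SNPs essentially unshrunk.
#'
#' If per-SNP dosage standard deviations `sd` are supplied, betas are moved to
#' the standardized scale before solving and back after, which makes the
#' joint-coefficient identity exact when SNP variances differ.
#'
#' @param beta marginal effect sizes of the locus members.
#' @param ld symmetric SNP correlation matrix with unit diagonal.
#' @param ridge non-negative ridge added to the diagonal (default 0.1).
#' @param sd optional per-SNP dosage standard deviations.
#' @return numeric vector of adjusted weights (per effect-allele dose).
#' @export
adjust_for_ld <- function(beta, ld, ridge = 0.1, sd = NULL) {
  m <- length(beta)
  ld <- as.matrix(ld)
  if (!all(dim(ld) == m))
    stop("LD matrix dimension must equal the number of betas", call. = FALSE)
  if (max(abs(ld - t(ld))) > 1e-8 || max(abs(diag(ld) - 1)) > 1e-8)
    stop("LD matrix must be symmetric with unit diagonal", call. = FALSE)
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  b <- if (is.null(sd)) beta else beta * sd
  w <- tryCatch(solve(ld + diag(ridge, m), b), error = function(e)
    stop("singular LD system; use a positive `ridge`", call. = FALSE))
  if (is.null(sd)) as.vector(w) else as.vector(w) / sd
}

# Correlation (and dosage SD) of a SNP set in a reference genotype panel.
.panel_ld <- function(geno, snp_ids) {
  X <- geno$dosages[, snp_ids, drop = FALSE]
  s <- apply(X, 2, stats::sd)
  R <- if (length(snp_ids) == 1L) matrix(1, 1, 1) else stats::cor(X)
  list(R = R, sd = s)
}

#' Harmonize summary-statistic alleles against a genotype panel
#'
#' Matches records to panel SNPs by id, aligns effect alleles (flipping the
#' sign of beta when effect/other alleles are swapped), and drops records
#' whose SNP is absent, whose allele pair does not match, or which are
#' strand-ambiguous (A/T or C/G). Dropped counts are reported via `message()`.
#'
#' @param records QTL record data.frame.
#' @param snp_meta panel SNP metadata (`snp_id, ea, oa`).
#' @return records aligned to the panel's effect alleles, with a `dropped`
#'   attribute holding the per-reason counts.
#' @export
harmonize_alleles <- function(records, snp_meta) {
  amb <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  idx <- match(records$snp_id, snp_meta$snp_id)
  missing <- is.na(idx)
  ambiguous <- !missing & amb(records$ea, records$oa)
  same <- !missing & !ambiguous & records$ea == snp_meta$ea[idx] &
    records$oa == snp_meta$oa[idx]
  flipped <- !missing & !ambiguous & records$ea == snp_meta$oa[idx] &
    records$oa == snp_meta$ea[idx]
  mismatch <- !missing & !ambiguous & !same & !flipped
  dropped <- c(missing = sum(missing), ambiguous = sum(ambiguous),
               mismatch = sum(mismatch))
  if (sum(dropped) > 0)
    message(sprintf("harmonization dropped %d record(s): %d missing, %d strand-ambiguous, %d allele-mismatched",
                    sum(dropped), dropped[1], dropped[2], dropped[3]))
  out <- records[same | flipped, , drop = FALSE]
  fl <- flipped[same | flipped]
  out$beta[fl] <- -out$beta[fl]
  tmp <- out$ea[fl]; out$ea[fl] <- out$oa[fl]; out$oa[fl] <- tmp
  attr(out, "dropped") <- dropped
  out
}

#' Build a clumped, LD-adjusted, HLA-masked QTL catalog
#'
#' The full preprocessing path from raw marginal summary statistics to the
#' locus sets from which scores are computed: allele harmonization against the
#' LD reference panel, cis/trans classification, p-value selection, HLA
#' masking (trans only), 200 kb single-linkage clumping, and per-locus ridge
#' LD adjustment of effect sizes using correlations from the reference panel.
#'
#' @param records raw QTL record data.frame.
#' @param ld_geno `genotype_matrix` used as the LD reference panel (in the
#'   synthetic pipeline, the reference cohort doubles as the panel).
#' @param cis_window,trans_p,cis_p,clump_window,ridge,hla_region tuning
#'   parameters; defaults follow the analysis constants (5 Mb cis window,
#'   trans p < 5e-8, cis p < 1e-6, 200 kb clumps, ridge 0.1, HLA chr6 25-34 Mb).
#' @return an object of class `qtl_catalog`: list with data.frames `trans`,
#'   `cis`, `hla` (each carrying `locus_id` and adjusted `weight` columns),
#'   the `counts` bookkeeping vector, and the parameters used.
#' @export
build_qtl_catalog <- function(records, ld_geno, cis_window = 5e6,
                              trans_p = 5e-8, cis_p = 1e-6,
                              clump_window = 2e5, ridge = 0.1,
                              hla_region = list(chrom = "6", start = 25e6, end = 34e6)) {
  stopifnot(inherits(ld_geno, "genotype_matrix"))
  n_input <- nrow(records)
  records <- harmonize_alleles(records, ld_geno$snp_meta)
  dropped <- attr(records, "dropped")
  sel <- select_qtls(records, trans_p = trans_p, cis_p = cis_p,
                     cis_window = cis_window)
  masked <- mask_hla(sel$trans, hla_region)
  n_subthreshold <- nrow(records) - nrow(sel$trans) - nrow(sel$cis)

  adjust_set <- function(recs) {
    if (nrow(recs) == 0) {
      recs$locus_id <- character(0); recs$weight <- numeric(0)
      return(recs)
    }
    recs <- clump_qtls(recs, window = clump_window)
    recs$weight <- NA_real_
    for (loc in unique(recs$locus_id)) {
      i <- which(recs$locus_id == loc)
      ld <- .panel_ld(ld_geno, recs$snp_id[i])
      recs$weight[i] <- adjust_for_ld(recs$beta[i], ld$R, ridge = ridge,
                                      sd = ld$sd)
    }
    recs
  }

  out <- structure(list(
    trans = adjust_set(masked$kept),
    cis = adjust_set(sel$cis),
    hla = adjust_set(masked$hla),
    counts = c(input = n_input, dropped, subthreshold = n_subthreshold,
               hla_masked = nrow(masked$hla),
               trans_retained = nrow(masked$kept), cis_retained = nrow(sel$cis)),
    params = list(cis_window = cis_window, trans_p = trans_p, cis_p = cis_p,
                  clump_window = clump_window, ridge = ridge,
                  hla_region = hla_region)),
    class = "qtl_catalog")
  out
}

#' @export
print.qtl_catalog <- function(x, ...) {
  nl <- function(d) length(unique(d$locus_id))
  cat(sprintf(paste0(
    "qtl_catalog: %d trans records in %d loci over %d genes; ",
    "%d cis records; %d HLA-region records\n"),
    nrow(x$trans), nl(x$trans), length(unique(x$trans$gene_id)),
    nrow(x$cis), nrow(x$hla)))
  invisible(x)
}
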