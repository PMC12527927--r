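#' Build GATE score definitions from a QTL catalog
#'
#' A gene qualifies for a trans-aggregated (GATE) score only when it has at
#' least `min_trans_loci` clumped trans loci: aggregating several trans-QTLs
#' raises the signal-to-noise ratio of the score and prevents a single strong
#' locus from dominating the association. Genes below the threshold are
#' excluded and counted.
#'
#' @param catalog a `qtl_catalog` (see [build_qtl_catalog()]).
#' @param min_trans_loci minimum number of trans loci (default 5).
#' @param score_type label for the score family, e.g. `"eGATE"` for
#'   expression-based or `"pGATE"` for protein-based scores.
#' @return an object of class `gate_definitions`: a named list of definitions,
#'   each with `gene_id`, `score_type`, `snps` (data.frame of members with
#'   adjusted weights), `n_trans_loci`; plus attributes `excluded` (genes
#'   failing the locus threshold) and `score_type`.
#' @export
build_definitions <- function(catalog, min_trans_loci = 5L, score_type = "eGATE") {
  stopifnot(inherits(catalog, "qtl_catalog"))
  tr <- catalog$trans
  defs <- list(); excluded <- character(0)
  for (g in unique(tr$gene_id)) {
    rows <- tr[tr$gene_id == g, , drop = FALSE]
    n_loci <- length(unique(rows$locus_id))
    if (n_loci < min_trans_loci) {
      excluded <- c(excluded, g)
      next
    }
    id <- paste0(score_type, ":", g)
    defs[[id]] <- list(gene_id = g, score_type = score_type,
                       snps = rows[, c("snp_id", "chrom", "pos", "ea", "oa",
                                       "locus_id", "beta", "weight")],
                       n_trans_loci = n_loci)
  }
  structure(defs, excluded = excluded, score_type = score_type,
            class = "gate_definitions")
}

#' Cis score definitions from a QTL catalog
#'
#' One definition per gene whose cis set qualified (at least one cis SNP below
#' the cis p threshold); no minimum locus count applies to cis scores.
#'
#' @inheritParams build_definitions
#' @export
cis_definitions <- function(catalog) {
  stopifnot(inherits(catalog, "qtl_catalog"))
  ci <- catalog$cis
  defs <- list()
  for (g in unique(ci$gene_id)) {
    rows <- ci[ci$gene_id == g, , drop = FALSE]
    id <- paste0("cis:", g)
    defs[[id]] <- list(gene_id = g, score_type = "cis",
                       snps = rows[, c("snp_id", "chrom", "pos", "ea", "oa",
                                       "locus_id", "beta", "weight")],
                       n_trans_loci = 0L)
  }
  structure(defs, excluded = character(0), score_type = "cis",
            class = "gate_definitions")
}

#' @export
print.gate_definitions <- function(x, ...) {
  cat(sprintf("%d %s score definition(s); %d gene(s) excluded by the trans-locus filter\n",
              length(x), attr(x, "score_type"), length(attr(x, "excluded"))))
  invisible(x)
}

#' Compute per-individual scores from definitions and genotype dosages
#'
#' Each score is the individual's effect-allele dosages summed over all
#' member SNPs, weighted by the LD-adjusted effect sizes, then standardized
#' (per score) on the standardization sample — by default the full cohort, so
#' association effect sizes read as log odds ratios per SD of score. Missing
#' dosages are mean-imputed per SNP before summation; SNPs absent from the
#' genotype panel are skipped with a message, and a definition with no
#' remaining SNPs is dropped with a warning.
#'
#' @param geno a `genotype_matrix`.
#' @param defs a `gate_definitions` object.
#' @param standardize standardize columns (default `TRUE`).
#' @param standardization optional list with `center` and `scale` vectors from
#'   a previous [compute_scores()] call, to project new individuals onto an
#'   existing scale.
#' @return an object of class `score_matrix`: list with `values`
#'   (individuals x scores, standardized), `center`, `scale`, and `provenance`
#'   (data.frame: score_id, gene_id, score_type, n_trans_loci, n_snps).
#' @export
compute_scores <- function(geno, defs, standardize = TRUE,
                           standardization = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(defs, "gate_definitions"))
  D <- geno$dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- mu[j]
  }
  keep <- list(); raw <- list()
  for (id in names(defs)) {
    d <- defs[[id]]
    present <- d$snps$snp_id %in% colnames(D)
    if (!all(present))
      message(sprintf("%s: %d of %d SNP(s) absent from genotypes, skipped",
                      id, sum(!present), length(present)))
    if (!any(present)) {
      warning(sprintf("%s: all member SNPs missing; definition dropped", id),
              call. = FALSE)
      next
    }
    s <- d$snps[present, , drop = FALSE]
    raw[[id]] <- as.vector(D[, s$snp_id, drop = FALSE] %*% s$weight)
    keep[[id]] <- data.frame(score_id = id, gene_id = d$gene_id,
                             score_type = d$score_type,
                             n_trans_loci = d$n_trans_loci, n_snps = nrow(s),
                             stringsAsFactors = FALSE)
  }
  if (length(raw) == 0)
    return(structure(list(values = matrix(0, nrow(D), 0,
                                          dimnames = list(rownames(D), NULL)),
                          center = numeric(0), scale = numeric(0),
                          provenance = do.call(rbind, keep)),
                     class = "score_matrix"))
  V <- do.call(cbind, raw)
  dimnames(V) <- list(rownames(D), names(raw))
  if (standardize) {
    if (is.null(standardization)) {
      center <- colMeans(V)
      scal <- apply(V, 2, stats::sd)
      scal[scal == 0] <- 1   # constant score: leave centred at zero
    } else {
      center <- standardization$center[colnames(V)]
      scal <- standardization$scale[colnames(V)]
    }
    V <- sweep(sweep(V, 2, center), 2, scal, "/")
  } else {
    center <- rep(0, ncol(V)); scal <- rep(1, ncol(V))
    names(center) <- names(scal) <- colnames(V)
  }
  structure(list(values = V, center = center, scale = scal,
                 provenance = do.call(rbind, keep)),
            class = "score_matrix")
}

#' HLA-specific trans scores
#'
#' The same weighted-dosage-sum contract as [compute_scores()], restricted to
#' the HLA-region record set held out by the mask; kept separate from GATE
#' outputs so that HLA-driven associations are never attributed to aggregated
#' genome-wide trans-effects.
#'
#' @param geno a `genotype_matrix`.
#' @param catalog a `qtl_catalog` whose `hla` slot holds the masked records.
#' @return a `score_matrix` of `hla_trans` scores (empty if no HLA records).
#' @export
hla_scores <- function(geno, catalog) {
  stopifnot(inherits(catalog, "qtl_catalog"))
  hl <- catalog$hla
  defs <- list()
  for (g in unique(hl$gene_id)) {
    rows <- hl[hl$gene_id == g, , drop = FALSE]
    id <- paste0("hla_trans:", g)
    defs[[id]] <- list(gene_id = g, score_type = "hla_trans",
                       snps = rows[, c("snp_id", "chrom", "pos", "ea", "oa",
                                       "locus_id", "beta", "weight")],
                       n_trans_loci = length(unique(rows$locus_id)))
  }
  defs <- structure(defs, excluded = character(0), score_type = "hla_trans",
                    class = "gate_definitions")
  compute_scores(geno, defs)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d individuals x %d score(s)\n",
              nrow(x$values), ncol(x$values)))
  if (ncol(x$values) > 0)
    cat("  types:", paste(unique(x$provenance$score_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.score_matrix <- function(x, ...) x$values
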