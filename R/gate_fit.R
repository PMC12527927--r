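#' Fit a genome-wide aggregated trans-effects (GATE) analysis
#'
#' The central fitting function: from marginal QTL summary statistics,
#' individual genotype dosages and a case-control phenotype table it
#' (1) builds the clumped, LD-adjusted, HLA-masked trans-locus catalog,
#' (2) constructs per-gene GATE scores (and cis and HLA-specific scores),
#' (3) tests every score for disease association by covariate-adjusted
#' logistic regression, (4) clusters correlated significant scores using
#' controls only, and (5) calls putative core genes.
#'
#' @param sumstats QTL summary-statistic data.frame (columns `snp_id, chrom,
#'   pos, ea, oa, gene_id, gene_chrom, gene_tss, beta, se, p`; see
#'   [read_sumstats()] for the TSV dialect).
#' @param genotypes a `genotype_matrix` for the analysis cohort.
#' @param phenotypes data.frame with `IID`, `STATUS` (0/1) and covariates.
#' @param covariates covariate column names (default: sex, cohort and all
#'   `PC*` columns present).
#' @param score_type label for the GATE score family (`"eGATE"` or `"pGATE"`).
#' @param cis_window cis/trans boundary in bp (default 5 Mb).
#' @param trans_p trans-QTL inclusion threshold (default 5e-8).
#' @param cis_p cis-score qualification threshold (default 1e-6).
#' @param clump_window clump chaining window in bp (default 200 kb).
#' @param min_trans_loci minimum trans loci per GATE score (default 5).
#' @param ridge LD-adjustment ridge (default 0.1).
#' @param hla_region HLA mask (default chr6, 25-34 Mb).
#' @param cor_threshold absolute-correlation threshold for clustering
#'   significant scores (default 0.25).
#' @param p_core core-gene significance threshold (default 1e-6).
#' @param ld_genotypes `genotype_matrix` used as LD/weight reference panel;
#'   defaults to the analysis genotypes, but an external reference cohort
#'   (e.g. the eQTL cohort in the synthetic pipeline) is preferred.
#' @return an object of class `gate` with components `catalog`, `definitions`,
#'   `scores`, `cis_scores`, `hla_score_matrix`, `associations` (GATE),
#'   `cis_associations`, `hla_associations`, `correlation` (significant-score
#'   correlations in controls), `clusters`, `calls`, `params`.
#' @seealso [summary.gate()] for a Table-1-style report, [gate_sim()] for
#'   synthetic inputs, [gate_mr()] for instrument-level follow-up.
#' @export
gate <- function(sumstats, genotypes, phenotypes,
                 covariates = default_covariates(phenotypes),
                 score_type = "eGATE",
                 cis_window = 5e6, trans_p = 5e-8, cis_p = 1e-6,
                 clump_window = 2e5, min_trans_loci = 5L, ridge = 0.1,
                 hla_region = list(chrom = "6", start = 25e6, end = 34e6),
                 cor_threshold = 0.25, p_core = 1e-6,
                 ld_genotypes = genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("IID", "STATUS") %in% names(phenotypes)))
  catalog <- build_qtl_catalog(sumstats, ld_genotypes,
                               cis_window = cis_window, trans_p = trans_p,
                               cis_p = cis_p, clump_window = clump_window,
                               ridge = ridge, hla_region = hla_region)
  defs <- build_definitions(catalog, min_trans_loci = min_trans_loci,
                            score_type = score_type)
  scores <- compute_scores(genotypes, defs)
  cis_scores <- compute_scores(genotypes, cis_definitions(catalog))
  hla_sm <- hla_scores(genotypes, catalog)

  assoc <- if (ncol(scores$values) > 0)
    associate_scores(scores, phenotypes, covariates) else NULL
  cis_assoc <- if (ncol(cis_scores$values) > 0)
    associate_scores(cis_scores, phenotypes, covariates) else NULL
  hla_assoc <- if (ncol(hla_sm$values) > 0)
    associate_scores(hla_sm, phenotypes, covariates) else NULL

  corr <- NULL; clusters <- NULL; calls <- NULL
  if (!is.null(assoc)) {
    sig <- assoc$score_id[!is.na(assoc$p) & assoc$p < p_core & !assoc$flagged]
    if (length(sig) >= 2) {
      sub <- scores
      sub$values <- scores$values[, sig, drop = FALSE]
      corr <- score_correlation_matrix(sub, phenotypes$STATUS == 0)
      clusters <- cluster_scores(corr, threshold = cor_threshold)
    } else if (length(sig) == 1) {
      clusters <- stats::setNames(1L, sig)
    }
    calls <- call_core_genes(assoc, clusters, p_threshold = p_core)
  }

  structure(list(catalog = catalog, definitions = defs, scores = scores,
                 cis_scores = cis_scores, hla_score_matrix = hla_sm,
                 associations = assoc, cis_associations = cis_assoc,
                 hla_associations = hla_assoc, correlation = corr,
                 clusters = clusters, calls = calls,
                 params = list(score_type = score_type, cis_window = cis_window,
                               trans_p = trans_p, cis_p = cis_p,
                               clump_window = clump_window,
                               min_trans_loci = min_trans_loci, ridge = ridge,
                               hla_region = hla_region,
                               cor_threshold = cor_threshold, p_core = p_core,
                               covariates = covariates)),
            class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  n_def <- length(x$definitions)
  n_sig <- if (is.null(x$calls)) 0L else sum(x$calls$status != "not_significant")
  n_core <- if (is.null(x$calls)) 0L else sum(x$calls$status == "putative_core")
  cat(sprintf(paste0(
    "GATE analysis (%s): %d score(s) tested, %d significant at p < %g,\n",
    "  %d putative core gene(s), %d in correlated clusters\n"),
    x$params$score_type, n_def, n_sig, x$params$p_core, n_core,
    n_sig - n_core))
  invisible(x)
}

#' Summarize a GATE fit as a candidate-core-gene table
#'
#' One row per GATE-scored gene: chromosome and transcription-site position,
#' number of trans loci, per-SD log odds ratio and p-value, the gene's cis
#' score association where one exists, and the core-gene call.
#'
#' @param object a `gate` fit.
#' @param all include non-significant genes (default `FALSE`: significant only,
#'   ordered by p).
#' @param ... unused.
#' @return data.frame of class `summary.gate`.
#' @export
summary.gate <- function(object, all = FALSE, ...) {
  a <- object$associations
  if (is.null(a)) return(invisible(NULL))
  gm <- object$catalog$trans[!duplicated(object$catalog$trans$gene_id),
                             c("gene_id", "gene_chrom", "gene_tss")]
  tab <- merge(a, gm, by = "gene_id", sort = FALSE)
  tab <- merge(tab, object$calls[, c("score_id", "status", "cluster_id")],
               by = "score_id", sort = FALSE)
  ci <- object$cis_associations
  if (!is.null(ci)) {
    ci <- ci[, c("gene_id", "log_or", "p")]
    names(ci)[2:3] <- c("cis_log_or", "cis_p")
    tab <- merge(tab, ci, by = "gene_id", all.x = TRUE, sort = FALSE)
  } else {
    tab$cis_log_or <- NA_real_; tab$cis_p <- NA_real_
  }
  out <- data.frame(gene = tab$gene_id, score_type = tab$score_type,
                    chr = tab$gene_chrom, tss_mb = round(tab$gene_tss / 1e6, 2),
                    n_trans_loci = tab$n_trans_loci,
                    log_or = round(tab$log_or, 2), p = signif(tab$p, 2),
                    cis_log_or = round(tab$cis_log_or, 2),
                    cis_p = signif(tab$cis_p, 2),
                    status = tab$status, cluster = tab$cluster_id,
                    stringsAsFactors = FALSE)
  if (!all) out <- out[out$status != "not_significant", , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary.gate", "data.frame")
  out
}

#' @export
print.summary.gate <- function(x, ...) {
  cat("Candidate core genes (per-SD log OR from covariate-adjusted logistic regression)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Per-SD log odds ratios of the GATE scores
#' @param object a `gate` fit.
#' @param ... unused.
#' @export
coef.gate <- function(object, ...) {
  a <- object$associations
  if (is.null(a)) return(numeric(0))
  stats::setNames(a$log_or, a$score_id)
}

#' Project new individuals onto fitted GATE scores
#'
#' Applies the fitted score definitions and the stored standardization
#' (mean/SD of the fitting cohort) to a new genotype matrix.
#'
#' @param object a `gate` fit.
#' @param genotypes a `genotype_matrix` for the new individuals.
#' @param ... unused.
#' @return a `score_matrix` on the fitting cohort's scale.
#' @export
predict.gate <- function(object, genotypes, ...) {
  compute_scores(genotypes, object$definitions,
                 standardization = list(center = object$scores$center,
                                        scale = object$scores$scale))
}

#' Heatmap of correlations among significant GATE scores
#'
#' Mirrors the usual presentation: scores ordered by hierarchical clustering,
#' correlations computed in controls.
#'
#' @param x a `gate` fit.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.gate <- function(x, ...) {
  if (is.null(x$correlation))
    stop("fewer than two significant scores; nothing to plot", call. = FALSE)
  stats::heatmap(x$correlation, symm = TRUE, scale = "none",
                 distfun = function(m) stats::as.dist(1 - abs(m)),
                 hclustfun = function(d) stats::hclust(d, method = "average"),
                 ...)
  invisible(x)
}

#' Extract MR instruments for one gene from a GATE fit
#'
#' Per trans locus of the gene, takes the lead SNP (smallest QTL p-value) as
#' the instrument: exposure effect and SE from the QTL summary statistics,
#' outcome effect and SE from a covariate-adjusted logistic regression of
#' disease on that SNP's dosage in the analysis cohort.
#'
#' @param object a `gate` fit.
#' @param gene gene identifier.
#' @param genotypes analysis-cohort `genotype_matrix`.
#' @param phenotypes phenotype data.frame (`IID`, `STATUS`, covariates).
#' @param covariates covariate names (default as in the fit).
#' @return data.frame `locus_id, snp_id, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome` suitable for [gate_mr()].
#' @export
extract_instruments <- function(object, gene, genotypes, phenotypes,
                                covariates = object$params$covariates) {
  stopifnot(inherits(object, "gate"))
  tr <- object$catalog$trans
  tr <- tr[tr$gene_id == gene, , drop = FALSE]
  if (nrow(tr) == 0) stop(sprintf("no trans loci for gene %s", gene), call. = FALSE)
  cov <- phenotypes[, intersect(covariates, names(phenotypes)), drop = FALSE]
  out <- lapply(unique(tr$locus_id), function(loc) {
    rows <- tr[tr$locus_id == loc, , drop = FALSE]
    lead <- rows[which.min(rows$p), ]
    x <- genotypes$dosages[, lead$snp_id]
    fit <- fit_score_association(x, phenotypes$STATUS, cov, score_id = loc)
    data.frame(locus_id = loc, snp_id = lead$snp_id,
               beta_exposure = lead$beta, se_exposure = lead$se,
               beta_outcome = fit$log_or, se_outcome = fit$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
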