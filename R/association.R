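#' Test one score for disease association
#'
#' Maximum-likelihood logistic regression of case-control status on a
#' standardized score, adjusting for covariates (the discovery analysis uses
#' sex, cohort and the first 10 genetic principal components; a
#' replication-style set of sex plus 20 PCs works the same way). The reported
#' effect is the score coefficient — the log odds ratio for one standard
#' deviation change in the score — with its Wald standard error and p-value.
#'
#' Degenerate (constant) covariates are dropped with a message. Perfect
#' separation is flagged: the result keeps the divergent estimate as a
#' sentinel and `flagged = TRUE`.
#'
#' @param score numeric vector (standardized score).
#' @param status 0/1 case-control outcome.
#' @param covariates optional data.frame of covariates.
#' @param score_id label carried into the result.
#' @return one-row data.frame: `score_id, log_or, se, p, n_cases, n_controls,
#'   flagged`.
#' @export
fit_score_association <- function(score, status, covariates = NULL,
                                  score_id = "score") {
  stopifnot(length(score) == length(status), all(status %in% 0:1))
  dat <- data.frame(.y = status, .s = score)
  if (!is.null(covariates)) {
    keep <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) > 1L,
                   logical(1))
    if (any(!keep))
      message(sprintf("dropping %d degenerate covariate(s): %s",
                      sum(!keep), paste(names(covariates)[!keep], collapse = ", ")))
    dat <- cbind(dat, covariates[, keep, drop = FALSE])
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  est <- co[".s", "Estimate"]; se <- co[".s", "Std. Error"]
  if (abs(est) > 15) flagged <- TRUE
  data.frame(score_id = score_id, log_or = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)),
             n_cases = sum(status == 1), n_controls = sum(status == 0),
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Association results for every column of a score matrix
#'
#' @param scores a `score_matrix`.
#' @param pheno phenotype data.frame with `IID`, `STATUS` and covariate
#'   columns; rows must align with the score matrix rows (matched by `IID`
#'   when both carry ids).
#' @param covariates character vector of covariate column names in `pheno`
#'   (default: `SEX`, `COHORT` and every `PC*` column present).
#' @return data.frame of per-score results with `gene_id` and `score_type`
#'   joined from the provenance.
#' @export
associate_scores <- function(scores, pheno,
                             covariates = default_covariates(pheno)) {
  stopifnot(inherits(scores, "score_matrix"))
  V <- scores$values
  if (!is.null(rownames(V)) && all(pheno$IID %in% rownames(V)))
    V <- V[match(pheno$IID, rownames(V)), , drop = FALSE]
  stopifnot(nrow(V) == nrow(pheno))
  cov <- pheno[, intersect(covariates, names(pheno)), drop = FALSE]
  out <- lapply(colnames(V), function(id)
    fit_score_association(V[, id], pheno$STATUS, cov, score_id = id))
  out <- do.call(rbind, out)
  merge(scores$provenance, out, by = "score_id", sort = FALSE)
}

#' Default covariate set for a phenotype table
#' @param pheno phenotype data.frame.
#' @export
default_covariates <- function(pheno) {
  c(intersect(c("SEX", "COHORT"), names(pheno)),
    grep("^PC[0-9]+$", names(pheno), value = TRUE))
}

#' Pearson correlation matrix of scores among controls
#'
#' Score correlations are computed in controls only, so that case enrichment
#' does not inflate the correlation among disease-associated scores.
#'
#' @param scores a `score_matrix`.
#' @param subset logical or integer index of the individuals to use
#'   (typically `pheno$STATUS == 0`); must select at least 3 rows.
#' @return symmetric correlation matrix; zero-variance scores are excluded
#'   with a warning.
#' @export
score_correlation_matrix <- function(scores, subset) {
  stopifnot(inherits(scores, "score_matrix"))
  V <- scores$values[subset, , drop = FALSE]
  if (nrow(V) < 3) stop("at least 3 individuals required", call. = FALSE)
  if (ncol(V) < 2) stop("at least 2 scores required", call. = FALSE)
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance score(s): %s",
                    sum(sds == 0), paste(colnames(V)[sds == 0], collapse = ", ")),
            call. = FALSE)
    V <- V[, sds > 0, drop = FALSE]
  }
  stats::cor(V)
}

#' Group correlated scores by hierarchical clustering
#'
#' Average-linkage hierarchical clustering on the distance `1 - |r|`, cut at
#' height `1 - threshold`, so that scores end up in one cluster when their
#' (average) absolute correlation reaches the threshold. Deterministic given
#' the input matrix.
#'
#' @param corr symmetric correlation matrix.
#' @param threshold absolute-correlation threshold (default 0.25).
#' @return named integer vector of cluster memberships.
#' @export
cluster_scores <- function(corr, threshold = 0.25) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (nrow(corr) == 1L) {
    cl <- 1L; names(cl) <- rownames(corr)
    return(cl)
  }
  hc <- stats::hclust(stats::as.dist(1 - abs(corr)), method = "average")
  stats::cutree(hc, h = 1 - threshold)
}

#' Call putative core genes from associations and score clusters
#'
#' A gene is called a putative core gene when its GATE score reaches the
#' significance threshold (default p < 1e-6) and is not part of a multi-gene
#' cluster of correlated scores. Correlated significant scores share
#' trans-QTLs, so the mediating gene cannot be distinguished; every member of
#' such a cluster is labelled `cluster_member` instead.
#'
#' @param results association data.frame (from [associate_scores()]), GATE
#'   scores only.
#' @param clusters named cluster membership vector over the significant
#'   scores (from [cluster_scores()] on their correlation submatrix); may be
#'   `NULL` when fewer than two scores are significant.
#' @param p_threshold core-gene significance threshold (default 1e-6).
#' @return data.frame: `score_id, gene_id, p, status, cluster_id,
#'   cluster_min_p` with status in `putative_core`, `cluster_member`,
#'   `not_significant`.
#' @export
call_core_genes <- function(results, clusters = NULL, p_threshold = 1e-6) {
  sig <- !is.na(results$p) & results$p < p_threshold & !results$flagged
  status <- ifelse(sig, "putative_core", "not_significant")
  cluster_id <- rep(NA_integer_, nrow(results))
  cluster_min_p <- results$p
  if (!is.null(clusters) && length(clusters) > 0) {
    idx <- match(results$score_id, names(clusters))
    cluster_id <- as.integer(clusters[idx])
    sizes <- table(clusters)
    multi <- sig & !is.na(cluster_id) & sizes[as.character(cluster_id)] > 1
    status[multi] <- "cluster_member"
    for (cl in unique(cluster_id[!is.na(cluster_id)]))
      cluster_min_p[!is.na(cluster_id) & cluster_id == cl] <-
        min(results$p[!is.na(cluster_id) & cluster_id == cl])
  }
  data.frame(score_id = results$score_id, gene_id = results$gene_id,
             p = results$p, status = status, cluster_id = cluster_id,
             cluster_min_p = cluster_min_p, stringsAsFactors = FALSE)
}
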