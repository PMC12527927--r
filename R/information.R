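#' Total genetic information for discrimination
#'
#' For a rare disease with additive genetic effects on the logistic scale,
#' the total genetic information for discriminating cases from non-cases
#' equals the logarithm of the sibling (first-degree) recurrence risk ratio;
#' in base 2 this is `log2(lambda_s)` bits. A recurrence risk ratio of 16
#' corresponds to 4 bits.
#'
#' @param lambda_s sibling recurrence risk ratio, >= 1.
#' @return information in bits.
#' @export
total_information <- function(lambda_s) {
  if (any(!is.finite(lambda_s)) || any(lambda_s < 1))
    stop("`lambda_s` must be finite and >= 1", call. = FALSE)
  log2(lambda_s)
}

#' Information contributed by one standardized predictor
#'
#' A predictor whose standardized log odds ratio for disease is `beta`
#' contributes `beta^2 / 2` natural-log units of expected weight of evidence,
#' i.e. `beta^2 / (2 log 2)` bits.
#'
#' @param beta standardized (per-SD) log odds ratio.
#' @return information in bits.
#' @export
predictor_information <- function(beta) {
  if (any(!is.finite(beta))) stop("`beta` must be finite", call. = FALSE)
  beta^2 / (2 * log(2))
}

#' Dilution-corrected information attributable to trans-effects on a gene
#'
#' A GATE score is an imperfect predictor of the trans-regulated component of
#' expression, so its observed association understates the underlying genetic
#' effect. The corrected information is
#' `I = beta^2 / (2 log 2) / (r2 / h2_trans)`,
#' where `r2` is the squared correlation between score and measured
#' expression and `h2_trans` the trans-heritability of expression; the
#' dilution factor `r2 / h2_trans` is the fraction of the trans-heritable
#' expression variance captured by the score.
#'
#' @param beta per-SD log odds ratio of the GATE score on disease.
#' @param r2 squared correlation between score and measured expression, in
#'   (0, `h2_trans`].
#' @param h2_trans trans-heritability of expression, in (0, 1).
#' @return an object of class `information_estimate`: list with `beta`, `r2`,
#'   `h2_trans`, `dilution`, `info_bits` (corrected) and `uncorrected_bits`.
#' @export
diluted_information <- function(beta, r2, h2_trans) {
  if (!is.finite(r2) || r2 <= 0)
    stop("`r2` must be positive; a zero-correlation score carries no usable signal",
         call. = FALSE)
  if (!is.finite(h2_trans) || h2_trans <= 0 || h2_trans >= 1)
    stop("`h2_trans` must lie in (0, 1)", call. = FALSE)
  if (r2 > h2_trans)
    stop("`r2` exceeds `h2_trans`: the score cannot explain more than the trans-heritable variance",
         call. = FALSE)
  un <- predictor_information(beta)
  dilution <- r2 / h2_trans
  structure(list(beta = beta, r2 = r2, h2_trans = h2_trans,
                 dilution = dilution, info_bits = un / dilution,
                 uncorrected_bits = un),
            class = "information_estimate")
}

#' @export
print.information_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "information for discrimination: %.2f bits ",
    "(uncorrected %.2f bits; dilution r2/h2_trans = %.3f)\n"),
    x$info_bits, x$uncorrected_bits, x$dilution))
  invisible(x)
}

#' Percentage of the total genetic effect
#'
#' @param info_bits information attributable to a predictor or pathway, bits.
#' @param total_bits total genetic information for discrimination, bits.
#' @return percentage `100 * info_bits / total_bits`.
#' @export
fraction_of_total <- function(info_bits, total_bits) {
  if (any(total_bits <= 0)) stop("`total_bits` must be positive", call. = FALSE)
  100 * info_bits / total_bits
}

#' Estimate the dilution factor of a score
#'
#' `r2` is the squared Pearson correlation between the GATE score and the
#' measured expression (or protein) level in paired individuals; the dilution
#' factor is `r2 / h2_trans`. `h2_trans` is an external input (from
#' expression-heritability studies, or from the ground truth in synthetic
#' runs), not estimated from case-control data. Sampling noise can push the
#' ratio above 1; it is then clipped with a warning. Estimates with
#' `r2` below `floor` are flagged unstable.
#'
#' @param score numeric score vector.
#' @param expression paired measured expression values.
#' @param h2_trans trans-heritability of the expression trait, in (0, 1\].
#' @param floor r2 below which the estimate is flagged unstable (default 1e-3).
#' @return list with `r2`, `dilution`, `unstable`.
#' @export
estimate_dilution <- function(score, expression, h2_trans, floor = 1e-3) {
  ok <- stats::complete.cases(score, expression)
  if (sum(ok) < 3)
    stop("at least 3 paired observations required", call. = FALSE)
  if (h2_trans <= 0 || h2_trans > 1)
    stop("`h2_trans` must lie in (0, 1]", call. = FALSE)
  r2 <- stats::cor(score[ok], expression[ok])^2
  dilution <- r2 / h2_trans
  if (dilution > 1) {
    warning("estimated dilution exceeds 1 (sampling noise); clipped to 1",
            call. = FALSE)
    dilution <- 1
  }
  list(r2 = r2, dilution = dilution, unstable = r2 < floor)
}

#' Combined score for a gene set (pathway)
#'
#' The mean of the standardized member scores, re-standardized — a single
#' pathway-level predictor whose association and dilution can be fed to
#' [diluted_information()]. Summing per-gene corrected estimates over
#' correlated genes would double-count shared trans-effects; a combined score
#' avoids that.
#'
#' @param scores a `score_matrix`.
#' @param members score ids to combine.
#' @return numeric standardized pathway score.
#' @export
pathway_score <- function(scores, members) {
  stopifnot(inherits(scores, "score_matrix"),
            all(members %in% colnames(scores$values)))
  s <- rowMeans(scores$values[, members, drop = FALSE])
  as.vector(scale(s))
}
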