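#' Per-instrument Wald ratio estimates
#'
#' For each instrument (one trans locus), the causal effect of the exposure
#' (gene product level) on the outcome (disease log odds) is the ratio of the
#' outcome effect to the exposure effect; its standard error follows from the
#' first-order delta method:
#' `SE^2 = se_out^2 / be^2 + bo^2 * se_exp^2 / be^4`.
#'
#' @param instruments data.frame with columns `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` (and optionally `locus_id`/`snp_id`).
#' @return the instruments with added `ratio` and `ratio_se` columns;
#'   instruments with `beta_exposure == 0` are excluded with a warning.
#' @export
wald_ratios <- function(instruments) {
  stopifnot(all(c("beta_exposure", "se_exposure", "beta_outcome",
                  "se_outcome") %in% names(instruments)))
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0))
    stop("standard errors must be positive", call. = FALSE)
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    warning(sprintf("excluding %d instrument(s) with zero exposure effect",
                    sum(zero)), call. = FALSE)
    instruments <- instruments[!zero, , drop = FALSE]
  }
  be <- instruments$beta_exposure; bo <- instruments$beta_outcome
  instruments$ratio <- bo / be
  instruments$ratio_se <- sqrt(instruments$se_outcome^2 / be^2 +
                                 bo^2 * instruments$se_exposure^2 / be^4)
  instruments
}

# inverse-gamma draw
.rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# One chain of the pleiotropy-marginalized MR Gibbs sampler.
# Model: bo_j ~ N(theta * be_j + alpha_j, s_j^2); alpha_j ~ N(0, tau^2 lam_j^2);
# lam_j ~ C+(0,1); tau ~ C+(0, tau0); theta ~ N(0, theta_prior_sd^2).
# Half-Cauchy scales are expanded via the inverse-gamma mixture
# lam^2 | nu ~ IG(1/2, 1/nu), nu ~ IG(1/2, 1) (and likewise tau^2 via xi),
# which makes every full conditional conjugate.
.mr_chain <- function(be, bo, s2, tau0, theta_prior_sd, n_iter, use_alpha) {
  m <- length(be)
  theta <- 0; alpha <- rep(0, m)
  lam2 <- rep(1, m); nu <- rep(1, m); tau2 <- tau0^2; xi <- 1
  draws_theta <- numeric(n_iter); draws_tau <- numeric(n_iter)
  draws_alpha <- matrix(0, n_iter, m)
  for (it in seq_len(n_iter)) {
    # theta | alpha
    prec <- sum(be^2 / s2) + 1 / theta_prior_sd^2
    mu <- sum(be * (bo - alpha) / s2) / prec
    theta <- stats::rnorm(1, mu, sqrt(1 / prec))
    if (use_alpha) {
      # alpha_j | theta, scales
      va <- 1 / (1 / s2 + 1 / (tau2 * lam2))
      alpha <- stats::rnorm(m, va * (bo - theta * be) / s2, sqrt(va))
      # local scales
      lam2 <- .rinvgamma(m, 1, 1 / nu + alpha^2 / (2 * tau2))
      nu <- .rinvgamma(m, 1, 1 + 1 / lam2)
      # global scale
      tau2 <- .rinvgamma(1, (m + 1) / 2, 1 / xi + sum(alpha^2 / lam2) / 2)
      xi <- .rinvgamma(1, 1, 1 / tau0^2 + 1 / tau2)
    }
    draws_theta[it] <- theta
    draws_tau[it] <- sqrt(tau2)
    draws_alpha[it, ] <- alpha
  }
  list(theta = draws_theta, tau = draws_tau, alpha = draws_alpha)
}

# split-chain potential scale reduction factor
.rhat <- function(chains) {
  half <- lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  })
  xs <- unlist(half, recursive = FALSE)
  n <- length(xs[[1]]); m <- length(xs)
  means <- vapply(xs, mean, numeric(1))
  vars <- vapply(xs, stats::var, numeric(1))
  W <- mean(vars); B <- n * stats::var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via the initial positive sequence of autocorrelations
.ess <- function(chains) {
  n <- length(chains[[1]]); m <- length(chains)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W < .Machine$double.eps) return(n * m)
  rho <- rep(0, n - 1)
  for (ch in chains) {
    a <- stats::acf(ch, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[-1]
    rho <- rho + a * stats::var(ch) / (W * m)
  }
  s <- 0
  for (t in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, (n * m) / (1 + 2 * s))
}

#' Pleiotropy-marginalized Mendelian randomization
#'
#' Estimates the causal slope of a gene product on disease from trans-QTL
#' instruments while marginalizing over unobserved direct (pleiotropic)
#' instrument effects. The model is
#' `beta_outcome_j ~ Normal(theta * beta_exposure_j + alpha_j, se_outcome_j^2)`
#' with a regularized global-local (horseshoe-type) shrinkage prior on the
#' pleiotropic effects `alpha_j`: most instruments are shrunk to (near) zero
#' pleiotropy while a gross outlier can escape shrinkage and is thereby
#' discounted from the slope estimate. Exposure effects are treated as fixed
#' (plug-in), the standard two-sample practice; optionally the outcome
#' variance is inflated by `theta^2 * se_exposure^2`.
#'
#' Sampling is by a conjugate Gibbs scheme (inverse-gamma scale-mixture
#' representation of the half-Cauchy scales), bit-reproducible under the
#' seed. With a single instrument the pleiotropy term is dropped (it would be
#' unidentifiable) and the posterior concentrates on the Wald ratio.
#'
#' @param instruments data.frame as in [wald_ratios()].
#' @param tau0 global pleiotropy prior scale on the log-OR scale (default 0.05).
#' @param chains number of MCMC chains (default 4).
#' @param iter iterations per chain (default 2000).
#' @param warmup burn-in discarded per chain (default `iter / 2`).
#' @param seed integer seed (mandatory for reproducibility).
#' @param theta_prior_sd SD of the Gaussian prior on the causal slope.
#' @param inflate_exposure_se if `TRUE`, add `theta^2 * se_exposure^2` to the
#'   outcome variances (re-evaluated at the running `theta`).
#' @return an object of class `gate_mr`: `theta_mean`, `theta_sd`, `interval`
#'   (2.5/97.5% posterior quantiles), `p_analog` (two-sided posterior tail
#'   probability analog, floored at `2/n_draws`), `wald` (per-instrument
#'   table), `alpha_mean`, `tau_mean`, `diagnostics` (`rhat`, `ess`,
#'   `divergences = 0` for Gibbs), `valid`, `draws` (posterior theta draws),
#'   and the call settings.
#' @export
gate_mr <- function(instruments, tau0 = 0.05, chains = 4L, iter = 2000L,
                    warmup = floor(iter / 2), seed = 1L,
                    theta_prior_sd = 10, inflate_exposure_se = FALSE) {
  wr <- wald_ratios(instruments)
  m <- nrow(wr)
  if (m == 0) stop("no usable instruments", call. = FALSE)
  if (m < 3)
    message(sprintf("only %d instrument(s); >= 3 recommended for a stable slope", m))
  be <- wr$beta_exposure; bo <- wr$beta_outcome
  use_alpha <- m > 1L
  set.seed(seed)
  ch_theta <- vector("list", chains); ch_tau <- vector("list", chains)
  alpha_sum <- rep(0, m)
  for (c in seq_len(chains)) {
    s2 <- wr$se_outcome^2
    if (inflate_exposure_se) {
      # crude two-pass: inflate at the Wald-ratio slope, then sample
      th0 <- sum(be * bo / s2) / sum(be^2 / s2)
      s2 <- s2 + th0^2 * wr$se_exposure^2
    }
    ch <- .mr_chain(be, bo, s2, tau0, theta_prior_sd, iter, use_alpha)
    post <- seq.int(warmup + 1L, iter)
    ch_theta[[c]] <- ch$theta[post]
    ch_tau[[c]] <- ch$tau[post]
    alpha_sum <- alpha_sum + colMeans(ch$alpha[post, , drop = FALSE])
  }
  draws <- unlist(ch_theta)
  rhat <- .rhat(ch_theta); ess <- .ess(ch_theta)
  valid <- rhat < 1.1 && ess >= 100
  p_analog <- max(2 * min(mean(draws > 0), mean(draws < 0)), 2 / length(draws))
  structure(list(theta_mean = mean(draws), theta_sd = stats::sd(draws),
                 interval = stats::quantile(draws, c(0.025, 0.975)),
                 p_analog = p_analog, wald = wr,
                 alpha_mean = alpha_sum / chains,
                 tau_mean = mean(unlist(ch_tau)),
                 diagnostics = list(rhat = rhat, ess = ess, divergences = 0L),
                 valid = valid, draws = draws,
                 settings = list(tau0 = tau0, chains = chains, iter = iter,
                                 warmup = warmup, seed = seed,
                                 theta_prior_sd = theta_prior_sd,
                                 inflate_exposure_se = inflate_exposure_se)),
            class = "gate_mr")
}

#' @export
print.gate_mr <- function(x, ...) {
  cat(sprintf(paste0(
    "Mendelian randomization (pleiotropy-marginalized), %d instrument(s)\n",
    "  causal slope: %.3f (sd %.3f), 95%% interval [%.3f, %.3f]\n",
    "  posterior tail p-analog: %.3g%s\n"),
    nrow(x$wald), x$theta_mean, x$theta_sd, x$interval[1], x$interval[2],
    x$p_analog,
    if (x$valid) "" else "  [diagnostics failed: interpret with caution]"))
  invisible(x)
}

#' @export
summary.gate_mr <- function(object, ...) {
  cat(sprintf("Diagnostics: split-Rhat %.3f, ESS %.0f, divergences %d\n",
              object$diagnostics$rhat, object$diagnostics$ess,
              object$diagnostics$divergences))
  cat(sprintf("Posterior pleiotropy scale (tau): %.4f\n", object$tau_mean))
  print(object)
  invisible(object$wald)
}

#' Instrument scatter with the posterior causal slope
#'
#' Exposure effects on the x-axis, outcome effects on the y-axis, marker area
#' inversely proportional to the Wald-ratio standard error, with the
#' posterior-mean slope through the origin and a one-SD slope band.
#'
#' @param x a `gate_mr` fit.
#' @param ... passed to [plot()].
#' @export
plot.gate_mr <- function(x, ...) {
  w <- x$wald
  cex <- 0.5 + 1.5 * (1 / w$ratio_se) / max(1 / w$ratio_se)
  plot(w$beta_exposure, w$beta_outcome, cex = cex, pch = 19,
       col = "steelblue", xlab = "effect on gene product (per allele)",
       ylab = "effect on disease (log OR per allele)", ...)
  xs <- range(c(0, w$beta_exposure))
  graphics::polygon(c(xs, rev(xs)),
                    c(xs * (x$theta_mean - x$theta_sd),
                      rev(xs) * (x$theta_mean + x$theta_sd)),
                    col = grDevices::adjustcolor("red", 0.2), border = NA)
  graphics::abline(0, x$theta_mean, col = "red")
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}
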