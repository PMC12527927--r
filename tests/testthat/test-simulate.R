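test_that("configuration invariants are enforced", {
  expect_error(gate_sim_config(block_rho = 1), "block_rho")
  expect_error(gate_sim_config(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(gate_sim_config(h2_trans = 0.7, h2_cis = 0.5), "exceed 1")
  expect_error(gate_sim_config(prevalence = 0), "prevalence")
  expect_error(gate_sim_config(n_blocks = 3), "too small")
})

test_that("genotypes are deterministic under a fixed seed and respect MAF range", {
  cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 1, seed = 11)
  g1 <- simulate_genotypes(cfg, n = 400, seed = 5)
  g2 <- simulate_genotypes(cfg, n = 400, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  g3 <- simulate_genotypes(cfg, n = 400, seed = 6)
  expect_false(identical(g1$dosages, g3$dosages))
  expect_true(all(g1$dosages %in% 0:2))
  # empirical allele frequency near its target
  af <- colMeans(g1$dosages) / 2
  expect_lt(max(abs(af - g1$snp_meta$maf)), 4 * sqrt(0.25 / (2 * 400)) + 0.02)
})

test_that("within-block LD matches the copula construction; blocks independent", {
  cfg0 <- gate_sim_config(n_core_genes = 1, n_null_genes = 1, block_rho = 0,
                          seed = 2)
  g0 <- simulate_genotypes(cfg0, n = 5000, seed = 2)
  C0 <- cor(g0$dosages[, 1:8])
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.05)

  cfg9 <- gate_sim_config(n_core_genes = 1, n_null_genes = 1, block_rho = 0.9,
                          seed = 2)
  g9 <- simulate_genotypes(cfg9, n = 5000, seed = 2)
  meta <- g9$snp_meta
  # independent oracle: dosage correlation of two thresholded latent Gaussians
  # with correlation rho, via numerical integration of
  # P11 = int phi(z) Phi((q2 - rho z)/sqrt(1-rho^2)) dz over z < q1
  expected_r <- function(p1, p2, rho) {
    q1 <- qnorm(p1); q2 <- qnorm(p2)
    p11 <- integrate(function(z)
      dnorm(z) * pnorm((q2 - rho * z) / sqrt(1 - rho^2)),
      -Inf, q1, rel.tol = 1e-10)$value
    (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  }
  for (b in unique(meta$block)[1:8]) {
    cols <- which(meta$block == b)
    for (j in seq_len(length(cols) - 1)) {
      got <- cor(g9$dosages[, cols[j]], g9$dosages[, cols[j + 1]])
      want <- expected_r(meta$maf[cols[j]], meta$maf[cols[j + 1]], 0.9)
      expect_equal(got, want, tolerance = 0.12)
      expect_gt(got, 0.3)
    }
  }
  # SNPs from different blocks stay uncorrelated
  first <- meta$snp_id[!duplicated(meta$block)][1:10]
  Cb <- cor(g9$dosages[, first])
  expect_lt(max(abs(Cb[upper.tri(Cb)])), 0.06)
})

test_that("expression realizes the configured variance decomposition", {
  cfg <- gate_sim_config(n_core_genes = 2, n_null_genes = 0, h2_trans = 0.4,
                         h2_cis = 0.1, seed = 9)
  g <- simulate_genotypes(cfg, n = 10000, seed = 9)
  truth <- make_architecture(cfg)
  e <- simulate_expression(g, truth, seed = 10)
  tv <- true_trans_values(g, truth)
  for (j in 1:2) {
    r2 <- summary(lm(e[, j] ~ tv[, j]))$r.squared
    expect_gt(r2, 0.35); expect_lt(r2, 0.45)
  }
  expect_equal(unname(apply(e, 2, var)), rep(1, 2), tolerance = 0.1)
})

test_that("zero trans-heritability and zero-noise limits behave", {
  # h2_trans ~ 0: expression uncorrelated with the trans genetic value
  cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 0, h2_trans = 1e-8,
                         h2_cis = 0, seed = 3)
  g <- simulate_genotypes(cfg, n = 2000, seed = 3)
  truth <- make_architecture(cfg)
  e <- simulate_expression(g, truth, seed = 4)
  tv <- true_trans_values(g, truth)
  expect_lt(abs(cor(e[, 1], tv[, 1])), 0.06)

  # degenerate no-noise case: expression equals the trans genetic value
  cfg1 <- gate_sim_config(n_core_genes = 1, n_null_genes = 0, h2_trans = 1,
                          h2_cis = 0, seed = 3)
  truth1 <- make_architecture(cfg1)
  g1 <- simulate_genotypes(cfg1, n = 500, seed = 3)
  e1 <- simulate_expression(g1, truth1, seed = 4)
  expect_equal(unname(e1[, 1]), unname(true_trans_values(g1, truth1)[, 1]))
})

test_that("case-control sampling hits requested counts and the null prevalence", {
  cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 0, core_log_or = 0,
                         prevalence = 0.5, seed = 21)
  g <- simulate_genotypes(cfg, n = 4000, seed = 21)
  truth <- make_architecture(cfg)
  ph <- simulate_case_control(g, NULL, truth, 1500, 1500, seed = 22)
  expect_equal(sum(ph$STATUS == 1), 1500)
  expect_equal(sum(ph$STATUS == 0), 1500)
  expect_true(all(c("SEX", "COHORT", "PC1", "PC10") %in% names(ph)))
  # raw case fraction before rejection ~ prevalence under zero effects
  set.seed(22)  # reproduce the internal draw scale: just check feasibility bound
  expect_error(simulate_case_control(g, NULL, truth, 3900, 3900, seed = 22),
               "simulate more individuals")
})

test_that("logistic refit on the true standardized genetic value recovers the log OR", {
  hits <- sapply(c(31, 131, 231), function(s) {
    cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 0,
                           core_log_or = 0.3, prevalence = 0.3, seed = s)
    g <- simulate_genotypes(cfg, n = 22000, seed = s)
    truth <- make_architecture(cfg)
    ph <- simulate_case_control(g, NULL, truth, 5000, 5000, seed = s + 1)
    idx <- attr(ph, "row_index")
    gv <- true_trans_values(g, truth)[idx, 1] / sqrt(truth$genes$h2_trans[1])
    est <- coef(summary(glm(ph$STATUS ~ gv, family = binomial())))["gv", ]
    abs(est["Estimate"] - 0.3) < 2 * est["Std. Error"]
  })
  expect_gte(sum(hits), 2)
})

test_that("reference summary statistics behave like marginal regressions", {
  cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 1, seed = 13)
  sim <- gate_sim(cfg, n_ref = 4000, n_cases = 300, n_controls = 300)
  ss <- sim$sumstats
  # causal SNPs strongly significant, null SNPs calibrated
  causal <- sim$truth$trans_effects$snp_id[
    sim$truth$trans_effects$gene_id == "G001"]
  sub <- ss[ss$gene_id == "G001", ]
  expect_true(all(sub$p[sub$snp_id %in% causal] < 1e-6))
  null_block_snps <- !(ss$snp_id %in% c(sim$truth$trans_effects$snp_id,
                                        sim$truth$cis_effects$snp_id))
  # SNPs in causal LD blocks correlate with causal SNPs; restrict to blocks
  # with no effect on either gene
  meta <- sim$panel
  eff_blocks <- meta$block[match(unique(c(sim$truth$trans_effects$snp_id,
                                          sim$truth$cis_effects$snp_id)),
                                 meta$snp_id)]
  pure_null <- ss[!(meta$block[match(ss$snp_id, meta$snp_id)] %in% eff_blocks), ]
  expect_gt(mean(abs(pure_null$beta) < 4 * pure_null$se), 0.99)
  # duplicated individuals rejected
  dup <- sim$geno_ref
  dup$sample_ids[2] <- dup$sample_ids[1]
  expect_error(reference_summary_stats(dup, sim$expr_ref), "duplicated")
})

test_that("a known marginal effect is recovered and RMSE shrinks with n_ref", {
  cfg <- gate_sim_config(n_core_genes = 4, n_null_genes = 0,
                         n_peripheral_loci_per_gene = 8, h2_trans = 0.3,
                         seed = 17)
  panel <- make_snp_panel(cfg)
  truth <- make_architecture(cfg)
  causal <- truth$trans_effects
  rmse <- sapply(c(2000, 5000, 10000), function(n) {
    g <- simulate_genotypes(cfg, n = n, seed = 100 + n, panel = panel)
    e <- simulate_expression(g, truth, seed = 200 + n)
    ss <- reference_summary_stats(g, e)
    est <- ss$beta[match(paste(causal$snp_id, causal$gene_id),
                         paste(ss$snp_id, ss$gene_id))]
    sqrt(mean((est - causal$effect)^2))
  })
  expect_true(all(diff(rmse) < 0))
  # individual effect within sampling error at the largest n
  expect_lt(rmse[3], 0.03)
})
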