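make_defs <- function(snp_ids, weights, gene = "G1", locus = NULL,
                      type = "eGATE", n_loci = 5L) {
  if (is.null(locus)) locus <- paste0("L", seq_along(snp_ids))
  d <- list(gene_id = gene, score_type = type,
            snps = data.frame(snp_id = snp_ids, chrom = "1",
                              pos = seq_along(snp_ids) * 1e6, ea = "A",
                              oa = "G", locus_id = locus,
                              beta = weights, weight = weights,
                              stringsAsFactors = FALSE),
            n_trans_loci = n_loci)
  structure(stats::setNames(list(d), paste0(type, ":", gene)),
            excluded = character(0), score_type = type,
            class = "gate_definitions")
}

tiny_geno <- function(D, ids = sprintf("rs%d", seq_len(ncol(D)))) {
  colnames(D) <- ids
  rownames(D) <- sprintf("I%d", seq_len(nrow(D)))
  structure(list(dosages = D,
                 snp_meta = data.frame(snp_id = ids, chrom = "1",
                                       pos = seq_along(ids) * 1e6, ea = "A",
                                       oa = "G", maf = 0.3),
                 sample_ids = rownames(D)),
            class = "genotype_matrix")
}

test_that("the trans-locus filter removes genes below the minimum", {
  s <- small_study()
  cat <- suppressMessages(build_qtl_catalog(s$sumstats, s$geno_ref))
  per_gene <- tapply(cat$trans$locus_id, cat$trans$gene_id,
                     function(x) length(unique(x)))
  d5 <- build_definitions(cat, min_trans_loci = 5)
  expect_setequal(vapply(d5, `[[`, "", "gene_id"), names(per_gene)[per_gene >= 5])
  expect_setequal(attr(d5, "excluded"), names(per_gene)[per_gene < 5])
  # boundary: exactly 5 loci qualifies
  if (any(per_gene == 5)) {
    g5 <- names(per_gene)[per_gene == 5][1]
    expect_equal(d5[[paste0("eGATE:", g5)]]$n_trans_loci, 5L)
  }
  # a 1-locus run yields a superset of the 5-locus run's definitions
  d1 <- build_definitions(cat, min_trans_loci = 1)
  expect_true(all(names(d5) %in% names(d1)))
})

test_that("raw scores are weighted dosage sums", {
  D <- matrix(c(2, 1, 0), ncol = 1)
  g <- tiny_geno(D)
  sm <- compute_scores(g, make_defs("rs1", 0.5), standardize = FALSE)
  expect_equal(unname(sm$values[, 1]), c(1.0, 0.5, 0))
  # all-zero weights give an all-zero score
  sm0 <- compute_scores(g, make_defs("rs1", 0), standardize = FALSE)
  expect_equal(unname(sm0$values[, 1]), c(0, 0, 0))
})

test_that("scores with adjusted weights reproduce joint-OLS fitted values", {
  cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 0, block_rho = 0.9,
                         seed = 60)
  g <- simulate_genotypes(cfg, n = 3000, seed = 60)
  cols <- which(g$snp_meta$block == g$snp_meta$block[1])[1:2]
  X <- g$dosages[, cols]
  set.seed(61)
  y <- X %*% c(0.2, 0.19) + rnorm(3000)
  joint <- coef(lm(y ~ X))[2:3]
  sm <- compute_scores(tiny_geno(X, colnames(X)),
                       make_defs(colnames(X), unname(joint), locus = c("L1", "L1")),
                       standardize = FALSE)
  expect_equal(unname(sm$values[, 1]), unname(as.vector(X %*% joint)),
               tolerance = 1e-6)
})

test_that("standardized scores are mean-zero unit-SD and weight-scale invariant", {
  set.seed(62)
  D <- matrix(rbinom(600, 2, 0.3), ncol = 3)
  g <- tiny_geno(D)
  w <- c(0.2, -0.1, 0.4)
  a <- compute_scores(g, make_defs(colnames(g$dosages), w))
  expect_equal(unname(colMeans(a$values)), 0, tolerance = 1e-12)
  expect_equal(unname(apply(a$values, 2, sd)), 1, tolerance = 1e-12)
  b <- compute_scores(g, make_defs(colnames(g$dosages), 7.3 * w))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("missing SNPs are skipped and missing dosages mean-imputed", {
  set.seed(63)
  D <- matrix(rbinom(400, 2, 0.4), ncol = 2)
  D[1, 2] <- NA
  g <- tiny_geno(D)
  defs <- make_defs(c("rs1", "rs2", "rs_gone"), c(0.5, 0.2, 9))
  expect_message(sm <- compute_scores(g, defs, standardize = FALSE), "absent")
  mu <- mean(D[-1, 2])
  expect_equal(unname(sm$values[1, 1]), 0.5 * D[1, 1] + 0.2 * mu)
  # all SNPs missing: definition dropped with a warning
  gone <- make_defs(c("nope1", "nope2"), c(1, 1))
  expect_warning(suppressMessages(compute_scores(g, gone)), "dropped")
})

test_that("a GATE score tracks the gene's trans-regulated expression", {
  s <- small_study(); fit <- small_fit()
  sc <- fit$scores$values[, "eGATE:G001"]
  r <- cor(sc, s$expr[, "G001"])
  expect_gt(r, 0.5)
  # squared correlation approaches h2_trans for a well-estimated score
  expect_gt(r^2, 0.25); expect_lt(r^2, 0.45)
})

test_that("HLA scores live apart and GATE columns ignore HLA genotypes", {
  s <- small_study(); fit <- small_fit()
  hla_snps <- s$panel$snp_id[s$panel$chrom == "6" & s$panel$pos >= 25e6 &
                               s$panel$pos <= 34e6]
  gate_snps <- unlist(lapply(fit$definitions, function(d) d$snps$snp_id))
  expect_length(intersect(gate_snps, hla_snps), 0)
  # permuting HLA-region genotype columns leaves every GATE score unchanged
  g2 <- s$geno
  set.seed(70)
  g2$dosages[, hla_snps] <- g2$dosages[sample(nrow(g2$dosages)), hla_snps]
  sm2 <- suppressMessages(compute_scores(g2, fit$definitions))
  expect_equal(sm2$values, fit$scores$values)
  # the hotspot's own score associates with disease
  expect_true(any(fit$hla_associations$p < 1e-6))
  # single-SNP HLA score contract
  D <- matrix(c(0, 1, 2), ncol = 1)
  g1 <- tiny_geno(D)
  cat1 <- list(hla = data.frame(snp_id = "rs1", chrom = "6", pos = 26e6,
                                ea = "A", oa = "G", gene_id = "GX",
                                locus_id = "GX:6:1", beta = 0.4, weight = 0.4),
               trans = data.frame(), cis = data.frame())
  class(cat1) <- "qtl_catalog"
  hs <- hla_scores(g1, cat1)
  raw <- c(0, 0.4, 0.8)
  expect_equal(unname(hs$values[, 1]), unname(scale(raw)[, 1]))
  # empty HLA record set gives an empty matrix
  cat0 <- cat1; cat0$hla <- cat1$hla[0, ]
  expect_equal(ncol(hla_scores(g1, cat0)$values), 0)
})
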