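test_that("cis/trans classification follows chromosome and distance rules", {
  r <- qtl_records(pos = 100e6, chrom = "1", gene_chrom = "2", gene_tss = 102e6)
  expect_equal(classify_cis_trans(r), "trans")
  r <- qtl_records(pos = 100e6, chrom = "2", gene_chrom = "2", gene_tss = 102e6)
  expect_equal(classify_cis_trans(r), "cis")
  # 6 Mb away on the same chromosome: at or beyond the 5 Mb window is trans
  r <- qtl_records(pos = 100e6, chrom = "2", gene_chrom = "2", gene_tss = 106e6)
  expect_equal(classify_cis_trans(r), "trans")
  r <- qtl_records(pos = 100e6, chrom = "2", gene_chrom = "2", gene_tss = 105e6)
  expect_equal(classify_cis_trans(r), "trans")  # boundary is inclusive
  r$gene_tss <- NA
  expect_error(classify_cis_trans(r), "missing gene TSS")
})

test_that("the HLA mask removes chr6 25-34 Mb records, endpoints inclusive", {
  r <- qtl_records(pos = c(26e6, 35e6, 30e6, 25e6, 34e6, 24999999),
                   chrom = c("6", "6", "5", "6", "6", "6"))
  m <- mask_hla(r)
  expect_equal(m$hla$pos, c(26e6, 25e6, 34e6))
  expect_equal(m$kept$pos, c(35e6, 30e6, 24999999))
  # chr prefix tolerated
  r2 <- qtl_records(pos = 30e6, chrom = "chr6")
  expect_equal(nrow(mask_hla(r2)$hla), 1)
})

test_that("clumping chains SNPs within 200 kb and matches the brute-force oracle", {
  r <- qtl_records(pos = c(1.0e6, 1.15e6, 1.4e6))
  cl <- clump_qtls(r)
  expect_true(same_partition(cl$locus_id, c(1, 1, 2)))
  # transitive chaining: pairwise gaps 190 kb give one clump of three
  r <- qtl_records(pos = c(1.0e6, 1.19e6, 1.38e6))
  expect_equal(length(unique(clump_qtls(r)$locus_id)), 1)
  # singleton
  expect_equal(length(unique(clump_qtls(qtl_records(1e6))$locus_id)), 1)
  # empty input passes through
  expect_equal(nrow(clump_qtls(qtl_records(numeric(0)))), 0)

  set.seed(404)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    pos <- sort(sample.int(3e6, n))
    got <- clump_qtls(qtl_records(pos), window = 2e5)
    expect_true(same_partition(got$locus_id, clump_oracle(got$pos, 2e5)))
  }
})

test_that("masking commutes with clumping up to re-partition", {
  set.seed(77)
  pos <- sort(sample(seq(20e6, 40e6, by = 1e4), 60))
  r <- qtl_records(pos, chrom = "6")
  a <- clump_qtls(mask_hla(r)$kept)
  b <- mask_hla(clump_qtls(r))$kept
  b <- clump_qtls(b[, setdiff(names(b), "locus_id")])
  expect_true(same_partition(a$locus_id[order(a$pos)],
                             b$locus_id[order(b$pos)]))
})

test_that("LD adjustment reduces to marginal betas at identity and shrinks with ridge", {
  b <- c(0.2, -0.1, 0.05)
  expect_equal(adjust_for_ld(b, diag(3), ridge = 0), b)
  norms <- sapply(c(0, 0.5, 2, 10, 100), function(rg)
    sqrt(sum(adjust_for_ld(b, diag(3), ridge = rg)^2)))
  expect_true(all(diff(norms) < 0))
  R <- matrix(c(1, 1, 1, 1), 2)  # singular
  expect_error(adjust_for_ld(c(0.1, 0.1), R, ridge = 0), "singular")
  expect_error(adjust_for_ld(b, diag(2)), "dimension")
})

test_that("ridge-zero LD adjustment equals joint OLS on a reference panel", {
  cfg <- gate_sim_config(n_core_genes = 1, n_null_genes = 0, block_rho = 0.9,
                         seed = 55)
  g <- simulate_genotypes(cfg, n = 10000, seed = 55)
  cols <- which(g$snp_meta$block == g$snp_meta$block[1])[1:2]
  X <- g$dosages[, cols]
  set.seed(56)
  y <- X %*% c(0.15, 0.1) + rnorm(10000)
  marg <- sapply(1:2, function(j) coef(lm(y ~ X[, j]))[2])
  joint <- coef(lm(y ~ X))[2:3]
  w <- adjust_for_ld(marg, cor(X), ridge = 0, sd = apply(X, 2, sd))
  expect_equal(unname(w), unname(joint), tolerance = 0.02)
})

test_that("block-diagonal LD decomposes into per-block solves", {
  set.seed(8)
  R1 <- cov2cor(crossprod(matrix(rnorm(30), 10, 3)))
  R2 <- cov2cor(crossprod(matrix(rnorm(40), 10, 4)))
  R <- rbind(cbind(R1, matrix(0, 3, 4)), cbind(matrix(0, 4, 3), R2))
  diag(R) <- 1
  b <- rnorm(7, 0, 0.1)
  w <- adjust_for_ld(b, R, ridge = 0.1)
  expect_equal(w[1:3], adjust_for_ld(b[1:3], R1, ridge = 0.1))
  expect_equal(w[4:7], adjust_for_ld(b[4:7], R2, ridge = 0.1))
})

test_that("selection applies the trans threshold and the cis qualification rule", {
  r <- rbind(
    qtl_records(1e6, chrom = "1", gene_chrom = "9", p = 1e-9),     # trans, keep
    qtl_records(2e6, chrom = "1", gene_chrom = "9", p = 1e-7),     # trans, drop
    qtl_records(1.1e6, chrom = "9", gene_tss = 1e6, p = 1e-5),     # cis, weak
    qtl_records(1.2e6, chrom = "9", gene_tss = 1e6, p = 1e-7))     # cis, strong
  sel <- select_qtls(r)
  expect_equal(sel$trans$pos, 1e6)
  expect_equal(sel$cis$pos, 1.2e6)
  # gene whose best cis p is 1e-5 gets no cis set
  weak <- qtl_records(1.1e6, chrom = "9", gene_tss = 1e6, p = 1e-5)
  expect_equal(nrow(select_qtls(weak)$cis), 0)
  empty <- select_qtls(qtl_records(numeric(0)))
  expect_equal(nrow(empty$trans), 0)
})

test_that("allele harmonization flips swapped alleles and drops ambiguous/mismatched", {
  meta <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                     ea = c("A", "A", "A", "C"), oa = c("G", "G", "T", "G"))
  rec <- qtl_records(c(1e6, 2e6, 3e6, 4e6))
  rec$snp_id <- c("s1", "s2", "s3", "s9")
  rec$ea <- c("A", "G", "A", "A"); rec$oa <- c("G", "A", "T", "G")
  rec$beta <- c(0.1, 0.2, 0.3, 0.4)
  out <- suppressMessages(harmonize_alleles(rec, meta))
  expect_equal(out$snp_id, c("s1", "s2"))
  expect_equal(out$beta, c(0.1, -0.2))   # s2 was swapped
  expect_equal(out$ea[2], "A")
  expect_equal(unname(attr(out, "dropped")),
               c(1, 1, 0))               # s9 missing, s3 ambiguous (A/T)
})

test_that("the catalog bookkeeping reconciles input with retained and dropped", {
  s <- small_study()
  cat <- suppressMessages(build_qtl_catalog(s$sumstats, s$geno_ref))
  ct <- cat$counts
  expect_equal(unname(ct["input"]),
               unname(ct["missing"] + ct["ambiguous"] + ct["mismatch"] +
                        ct["subthreshold"] + ct["hla_masked"] +
                        ct["trans_retained"] + ct["cis_retained"]))
  expect_true(all(table(cat$trans$gene_id) >= 1))
  # no trans record sits inside the HLA mask
  expect_false(any(cat$trans$chrom == "6" & cat$trans$pos >= 25e6 &
                     cat$trans$pos <= 34e6))
})
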