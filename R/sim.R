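#' Configuration for the synthetic omnigenic architecture
#'
#' Defines the generative model used throughout the package's tests and
#' example pipelines: an LD-blocked SNP panel, a sparse set of core genes on
#' which many peripheral trans-acting loci converge, optional genes that share
#' all their trans loci (an interferon-signature-like block), null genes with
#' trans-regulation but no disease effect, and an optional HLA-like
#' trans-hotspot with a direct disease effect.
#'
#' Expression for each gene is generated on a unit-variance scale as
#' trans genetic value + cis genetic value + Gaussian noise, with the genetic
#' variance fractions fixed at `h2_trans` and `h2_cis`. Disease status follows
#' a logistic model in the standardized trans genetic values of the core genes
#' (one shared latent for the shared block), so that logistic regression on
#' the true genetic value is correctly specified.
#'
#' @param n_snps total number of SNPs in the panel; `NULL` derives it as
#'   `snps_per_block` SNPs for every block.
#' @param n_blocks number of LD blocks; `NULL` derives the minimum needed for
#'   the requested genes plus two spare background blocks.
#' @param snps_per_block SNPs per LD block (used when deriving `n_snps`).
#' @param block_rho latent AR(1) haplotype correlation within a block, in \[0,1).
#' @param maf_range range of minor allele frequencies, within \[0.05, 0.5\]
#'   (mirrors the >= 5% MAF filter applied to the real genotype data).
#' @param n_core_genes number of true core genes with independent instruments.
#' @param n_null_genes genes with trans-regulation but no disease effect.
#' @param n_shared_genes genes sharing one common set of trans loci (0 disables).
#' @param n_peripheral_loci_per_gene trans loci (LD blocks) per gene.
#' @param trans_effect_sd scale of raw per-locus effects before normalization.
#' @param h2_trans proportion of expression variance from trans loci, in (0,1].
#' @param h2_cis proportion of expression variance from the cis locus, in \[0,1).
#' @param core_log_or per-SD log odds ratio of each core gene's trans genetic
#'   value on disease (also used for the shared-block latent).
#' @param prevalence disease probability at mean liability.
#' @param hla_like_region `NULL`, or a list with elements `chrom`, `start`,
#'   `end`, `trans_h2` (extra expression variance contributed by the hotspot
#'   SNP to every gene) and `disease_log_or` (direct effect on liability).
#'   `hla_hotspot()` builds a standard one.
#' @param confound_covariates if `TRUE`, sex and cohort enter the liability
#'   (for robustness tests); by default they are pure nuisance labels.
#' @param n_pcs number of nuisance principal-component columns to emit.
#' @param seed integer seed governing the panel, architecture and all cohorts.
#' @return an object of class `gate_sim_config` (a validated list).
#' @seealso [gate_sim()] for one-call generation of a full study.
#' @export
gate_sim_config <- function(n_snps = NULL, n_blocks = NULL, snps_per_block = 4L,
                            block_rho = 0.9, maf_range = c(0.05, 0.5),
                            n_core_genes = 5L, n_null_genes = 8L,
                            n_shared_genes = 0L,
                            n_peripheral_loci_per_gene = 8L,
                            trans_effect_sd = 1, h2_trans = 0.4, h2_cis = 0.1,
                            core_log_or = 0.3, prevalence = 0.1,
                            hla_like_region = NULL,
                            confound_covariates = FALSE, n_pcs = 10L,
                            seed = 1L) {
  if (!is.numeric(block_rho) || block_rho < 0 || block_rho >= 1)
    stop("`block_rho` must lie in [0, 1)", call. = FALSE)
  if (length(maf_range) != 2L || any(maf_range < 0.05) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("`maf_range` must be an increasing pair within [0.05, 0.5]", call. = FALSE)
  if (h2_trans <= 0 || h2_trans > 1 || h2_cis < 0 || h2_cis >= 1)
    stop("`h2_trans` must be in (0, 1] and `h2_cis` in [0, 1)", call. = FALSE)
  hot_h2 <- if (is.null(hla_like_region)) 0 else hla_like_region$trans_h2
  if (h2_trans + h2_cis + hot_h2 > 1)
    stop("h2_trans + h2_cis (+ hotspot trans_h2) must not exceed 1", call. = FALSE)
  counts <- c(n_core_genes = n_core_genes, n_null_genes = n_null_genes,
              n_peripheral_loci_per_gene = n_peripheral_loci_per_gene,
              snps_per_block = snps_per_block)
  if (any(counts[c(1, 3, 4)] < 1) || n_null_genes < 0 || n_shared_genes < 0)
    stop("gene/locus counts must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be in (0, 1)", call. = FALSE)

  n_genes <- n_core_genes + n_shared_genes + n_null_genes
  base <- n_genes +                                       # one cis block per gene
    (n_core_genes + n_null_genes) * n_peripheral_loci_per_gene +
    (n_shared_genes > 0L) * n_peripheral_loci_per_gene +
    !is.null(hla_like_region)
  # spare blocks: trans loci must avoid the target gene's chromosome (and the
  # shared set avoids every shared gene's chromosome), so keep enough slack
  # that an excluded chromosome cannot exhaust the pool
  spare <- 2L
  repeat {
    req <- 2L + ceiling((base + spare) / 22) * max(1L, n_shared_genes)
    if (spare >= req) break
    spare <- req
  }
  need <- base + spare
  if (is.null(n_blocks)) n_blocks <- need
  if (n_blocks < need)
    stop(sprintf("`n_blocks` = %d is too small for this architecture (need >= %d)",
                 n_blocks, need), call. = FALSE)
  if (is.null(n_snps)) n_snps <- n_blocks * snps_per_block
  if (n_snps < n_blocks)
    stop("`n_snps` must be at least `n_blocks`", call. = FALSE)

  structure(list(
    n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block), block_rho = block_rho,
    maf_range = maf_range, n_core_genes = as.integer(n_core_genes),
    n_null_genes = as.integer(n_null_genes),
    n_shared_genes = as.integer(n_shared_genes),
    n_peripheral_loci_per_gene = as.integer(n_peripheral_loci_per_gene),
    trans_effect_sd = trans_effect_sd, h2_trans = h2_trans, h2_cis = h2_cis,
    core_log_or = core_log_or, prevalence = prevalence,
    hla_like_region = hla_like_region,
    confound_covariates = isTRUE(confound_covariates),
    n_pcs = as.integer(n_pcs), seed = as.integer(seed)),
    class = "gate_sim_config")
}

#' Standard HLA-like trans-hotspot specification
#'
#' A single locus inside chr6:25-34 Mb with trans effects on every simulated
#' gene and a direct effect on disease liability — the confounding pattern
#' that motivates excluding the HLA region from trans-score aggregation.
#'
#' @param trans_h2 expression variance contributed by the hotspot SNP per gene.
#' @param disease_log_or direct per-SD log odds ratio on liability.
#' @export
hla_hotspot <- function(trans_h2 = 0.05, disease_log_or = 0.4) {
  list(chrom = "6", start = 25e6, end = 34e6,
       trans_h2 = trans_h2, disease_log_or = disease_log_or)
}

# Lay out LD blocks on chromosomes 1..22. Blocks are 8 Mb apart on a
# chromosome (far beyond the 200 kb clump window, and beyond the 5 Mb cis
# window for any other block's TSS); SNPs within a block are 5 kb apart.
# Regular blocks on chromosome 6 start at 40 Mb so that none falls inside the
# 25-34 Mb hotspot mask; an optional hotspot block sits at 28 Mb.
.layout_blocks <- function(config) {
  n_reg <- config$n_blocks - !is.null(config$hla_like_region)
  chrom <- as.character(((seq_len(n_reg) - 1L) %% 22L) + 1L)
  slot <- (seq_len(n_reg) - 1L) %/% 22L
  start <- 10e6 + slot * 8e6
  start[chrom == "6"] <- 40e6 + slot[chrom == "6"] * 8e6
  blocks <- data.frame(block = seq_len(n_reg), chrom = chrom, start = start,
                       hotspot = FALSE, stringsAsFactors = FALSE)
  if (!is.null(config$hla_like_region)) {
    h <- config$hla_like_region
    blocks <- rbind(blocks, data.frame(
      block = n_reg + 1L, chrom = as.character(h$chrom),
      start = (h$start + h$end) / 2 - 1e6, hotspot = TRUE))
  }
  blocks
}

#' Build the SNP panel for a synthetic configuration
#'
#' Deterministic given `config$seed`: block layout, per-SNP positions, allele
#' pairs (non-strand-ambiguous by construction) and allele frequencies.
#'
#' @param config a [gate_sim_config()].
#' @return a data.frame of per-SNP metadata with one row per SNP
#'   (`snp_id, chrom, pos, ea, oa, maf, block`).
#' @export
make_snp_panel <- function(config) {
  stopifnot(inherits(config, "gate_sim_config"))
  set.seed(config$seed)
  blocks <- .layout_blocks(config)
  per <- rep(config$snps_per_block, nrow(blocks))
  # distribute any remainder SNPs over the first blocks
  extra <- config$n_snps - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  idx <- rep(seq_len(nrow(blocks)), per)
  offset <- sequence(per) - 1L
  pairs <- matrix(c("A", "G", "A", "C", "C", "T", "G", "T"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, config$n_snps, replace = TRUE)
  data.frame(
    snp_id = sprintf("rs%05d", seq_len(config$n_snps)),
    chrom = blocks$chrom[idx],
    pos = blocks$start[idx] + offset * 5000,
    ea = pairs[pick, 1], oa = pairs[pick, 2],
    maf = stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2]),
    block = blocks$block[idx],
    hotspot = blocks$hotspot[idx],
    stringsAsFactors = FALSE)
}

#' Simulate genotype dosages with block AR(1) linkage disequilibrium
#'
#' Each individual is the sum of two haplotypes. A haplotype is generated from
#' a latent Gaussian AR(1) process within each LD block (correlation
#' `block_rho` between adjacent SNPs, independence across blocks), thresholded
#' at the allele-frequency quantile, so each SNP's dosage is marginally
#' Binomial(2, maf) while neighbours are correlated.
#'
#' @param config a [gate_sim_config()].
#' @param n number of individuals.
#' @param seed seed for this cohort (defaults to `config$seed`); the panel
#'   itself is always derived from `config$seed`.
#' @param panel optional precomputed [make_snp_panel()] output.
#' @param id_prefix prefix for sample identifiers.
#' @return an object of class `genotype_matrix`: a list with `dosages`
#'   (n x SNP matrix with dimnames), `snp_meta` and `sample_ids`.
#' @export
simulate_genotypes <- function(config, n = 1000L, seed = config$seed,
                               panel = make_snp_panel(config),
                               id_prefix = "S") {
  stopifnot(inherits(config, "gate_sim_config"), n >= 1)
  force(panel)   # the panel draws from config$seed; resolve it before reseeding
  set.seed(seed)
  rho <- config$block_rho
  m <- nrow(panel)
  D <- matrix(0L, nrow = n, ncol = m)
  q <- stats::qnorm(panel$maf)
  for (b in unique(panel$block)) {
    cols <- which(panel$block == b)
    z <- stats::rnorm(2L * n)
    for (j in seq_along(cols)) {
      if (j > 1L) z <- rho * z + sqrt(1 - rho^2) * stats::rnorm(2L * n)
      h <- z < q[cols[j]]
      D[, cols[j]] <- as.integer(h[seq_len(n)] + h[n + seq_len(n)])
    }
  }
  dimnames(D) <- list(sprintf("%s%06d", id_prefix, seq_len(n)), panel$snp_id)
  structure(list(dosages = D, snp_meta = panel, sample_ids = rownames(D)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d LD blocks)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snp_meta$block))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by individuals
#' @param x a `genotype_matrix`.
#' @param i row (individual) index.
#' @param ... unused.
#' @export
subset_individuals <- function(x, i, ...) {
  stopifnot(inherits(x, "genotype_matrix"))
  x$dosages <- x$dosages[i, , drop = FALSE]
  x$sample_ids <- rownames(x$dosages)
  x
}

# Draw the true regulatory architecture over a SNP panel. Per-SNP effects are
# normalized analytically (causal SNPs sit in distinct LD blocks, hence are
# independent with dosage variance 2p(1-p)) so the trans genetic value has
# variance exactly h2_trans in the population.
.make_architecture <- function(config, panel) {
  set.seed(config$seed + 7L)
  n_core <- config$n_core_genes; n_sh <- config$n_shared_genes
  n_null <- config$n_null_genes
  n_genes <- n_core + n_sh + n_null
  npl <- config$n_peripheral_loci_per_gene
  v <- 2 * panel$maf * (1 - panel$maf)

  blocks <- unique(panel$block[!panel$hotspot])
  block_chrom <- panel$chrom[match(blocks, panel$block)]
  used <- logical(length(blocks))

  take <- function(k, exclude_chrom = NULL) {
    ok <- which(!used & !(block_chrom %in% exclude_chrom))
    if (length(ok) < k) stop("not enough LD blocks for architecture", call. = FALSE)
    sel <- ok[seq_len(k)]
    used[sel] <<- TRUE
    blocks[sel]
  }
  mid_snp <- function(b) {
    cols <- which(panel$block == b)
    cols[ceiling(length(cols) / 2)]
  }

  roles <- c(rep("core", n_core), rep("shared", n_sh), rep("null", n_null))
  genes <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)), role = roles,
                      chrom = NA_character_, tss = NA_real_,
                      h2_trans = config$h2_trans, h2_cis = config$h2_cis,
                      log_or = ifelse(roles == "core", config$core_log_or, 0),
                      stringsAsFactors = FALSE)

  # cis block per gene fixes the gene's chromosome and TSS
  cis_blocks <- take(n_genes)
  genes$chrom <- block_chrom[match(cis_blocks, blocks)]
  genes$tss <- panel$pos[match(cis_blocks, panel$block)] + 1000

  shared_blocks <- if (n_sh > 0) take(npl, exclude_chrom = genes$chrom[genes$role == "shared"])
  u_shared <- if (n_sh > 0) stats::rnorm(npl, 0, config$trans_effect_sd)

  trans <- vector("list", n_genes)
  cis <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (roles[g] == "shared") {
      bl <- shared_blocks
      u <- u_shared + stats::rnorm(npl, 0, 0.15 * config$trans_effect_sd)
    } else {
      bl <- take(npl, exclude_chrom = genes$chrom[g])
      u <- stats::rnorm(npl, 0, config$trans_effect_sd)
    }
    snp_idx <- vapply(bl, mid_snp, integer(1))
    b <- u * sqrt(config$h2_trans / sum(u^2 * v[snp_idx]))
    trans[[g]] <- data.frame(gene_id = genes$gene_id[g], snp_index = snp_idx,
                             snp_id = panel$snp_id[snp_idx], effect = b,
                             stringsAsFactors = FALSE)
    ci <- mid_snp(cis_blocks[g])
    cis[[g]] <- data.frame(gene_id = genes$gene_id[g], snp_index = ci,
                           snp_id = panel$snp_id[ci],
                           effect = if (config$h2_cis > 0)
                             sqrt(config$h2_cis / v[ci]) else 0,
                           stringsAsFactors = FALSE)
  }
  trans <- do.call(rbind, trans); cis <- do.call(rbind, cis)

  # disease drivers: one per core gene (standardized trans value), one for the
  # whole shared block, one for the hotspot SNP if present
  drivers <- list()
  for (g in which(roles == "core")) {
    w <- trans$effect[trans$gene_id == genes$gene_id[g]] / sqrt(config$h2_trans)
    drivers[[length(drivers) + 1L]] <- list(
      name = genes$gene_id[g], snp_index = trans$snp_index[trans$gene_id == genes$gene_id[g]],
      weights = w, log_or = config$core_log_or)
  }
  hotspot <- NULL
  if (any(panel$hotspot)) {
    hcols <- which(panel$hotspot)
    hsnp <- hcols[ceiling(length(hcols) / 2)]
    h <- config$hla_like_region
    hot_eff <- sample(c(-1, 1), n_genes, replace = TRUE) * sqrt(h$trans_h2 / v[hsnp])
    hotspot <- list(snp_index = hsnp, snp_id = panel$snp_id[hsnp],
                    trans_effects = hot_eff, trans_h2 = h$trans_h2,
                    disease_log_or = h$disease_log_or)
    drivers[[length(drivers) + 1L]] <- list(
      name = "hotspot", snp_index = hsnp, weights = 1 / sqrt(v[hsnp]),
      log_or = h$disease_log_or)
  }
  if (n_sh > 0) {
    snp_idx <- vapply(shared_blocks, mid_snp, integer(1))
    w <- u_shared * sqrt(config$h2_trans / sum(u_shared^2 * v[snp_idx])) /
      sqrt(config$h2_trans)
    drivers[[length(drivers) + 1L]] <- list(
      name = "shared_block", snp_index = snp_idx, weights = w,
      log_or = config$core_log_or)
  }

  structure(list(genes = genes, trans_effects = trans, cis_effects = cis,
                 drivers = drivers, hotspot = hotspot,
                 prevalence = config$prevalence,
                 confound_covariates = config$confound_covariates,
                 n_pcs = config$n_pcs, h2_trans = config$h2_trans,
                 h2_cis = config$h2_cis, seed = config$seed),
            class = "true_architecture")
}

#' Ground-truth regulatory architecture for a configuration
#'
#' Exposes the causal trans/cis SNPs, effect sizes, disease drivers and
#' hotspot membership used by the simulator, for parameter-recovery tests.
#'
#' @param config a [gate_sim_config()].
#' @param panel optional precomputed [make_snp_panel()] output.
#' @export
make_architecture <- function(config, panel = make_snp_panel(config)) {
  .make_architecture(config, panel)
}

#' True trans genetic values
#'
#' @param geno a `genotype_matrix`.
#' @param truth a `true_architecture`.
#' @return individuals x genes matrix of per-gene trans genetic values
#'   (population variance `h2_trans` by construction).
#' @export
true_trans_values <- function(geno, truth) {
  genes <- truth$genes$gene_id
  out <- matrix(0, nrow(geno$dosages), length(genes),
                dimnames = list(geno$sample_ids, genes))
  for (g in genes) {
    tr <- truth$trans_effects[truth$trans_effects$gene_id == g, ]
    out[, g] <- geno$dosages[, tr$snp_index, drop = FALSE] %*% tr$effect
  }
  out
}

#' Simulate expression (or protein) levels from the true architecture
#'
#' expression = trans genetic value + cis genetic value (+ hotspot trans
#' effect) + Gaussian noise, on a unit-variance scale; realized genetic
#' variance fractions match the configured `h2_trans`/`h2_cis` up to
#' Monte-Carlo error.
#'
#' @param geno a `genotype_matrix`.
#' @param truth a `true_architecture` consistent with `geno`.
#' @param seed seed for the noise draw.
#' @return individuals x genes matrix with a `gene_meta` attribute
#'   (`gene_id, chrom, tss, h2_trans, h2_cis, role`).
#' @export
simulate_expression <- function(geno, truth, seed = truth$seed + 11L) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(truth, "true_architecture"))
  if (max(truth$trans_effects$snp_index) > ncol(geno$dosages))
    stop("architecture refers to SNPs beyond the genotype panel", call. = FALSE)
  set.seed(seed)
  n <- nrow(geno$dosages)
  genes <- truth$genes
  E <- true_trans_values(geno, truth)
  hot_h2 <- if (is.null(truth$hotspot)) 0 else truth$hotspot$trans_h2
  for (g in seq_len(nrow(genes))) {
    ci <- truth$cis_effects[truth$cis_effects$gene_id == genes$gene_id[g], ]
    val <- E[, g] + geno$dosages[, ci$snp_index] * ci$effect
    if (!is.null(truth$hotspot))
      val <- val + geno$dosages[, truth$hotspot$snp_index] *
        truth$hotspot$trans_effects[g]
    noise_var <- 1 - genes$h2_trans[g] - genes$h2_cis[g] - hot_h2
    if (noise_var > 1e-12) val <- val + stats::rnorm(n, 0, sqrt(noise_var))
    E[, g] <- val
  }
  attr(E, "gene_meta") <- genes[, c("gene_id", "chrom", "tss", "h2_trans",
                                    "h2_cis", "role")]
  E
}

#' Simulate case-control status and nuisance covariates
#'
#' Disease is drawn from a logistic model on the standardized trans genetic
#' values of the disease-driver set (core genes, the shared block's common
#' latent, and the hotspot SNP if configured), with intercept
#' `qlogis(prevalence)`. Exactly `n_cases` cases and `n_controls` controls are
#' then drawn by rejection from the simulated cohort. Sex and cohort are
#' nuisance labels with no liability effect unless the configuration enables
#' confounding.
#'
#' @param geno a `genotype_matrix` (the sampling pool).
#' @param expression matching expression matrix (carried through, unused by the
#'   liability model, which acts on genetic values).
#' @param truth a `true_architecture`.
#' @param n_cases,n_controls required counts.
#' @param seed seed for status, covariates and subsampling.
#' @return a data.frame with columns `IID, STATUS, SEX, COHORT, PC1..PCk`,
#'   with attribute `row_index` giving the selected rows of `geno`.
#' @export
simulate_case_control <- function(geno, expression, truth, n_cases, n_controls,
                                  seed = truth$seed + 23L) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(truth, "true_architecture"))
  set.seed(seed)
  n <- nrow(geno$dosages)
  eta <- rep(stats::qlogis(truth$prevalence), n)
  for (d in truth$drivers) {
    # centre at the population dosage mean so qlogis(prevalence) really is
    # the liability intercept at mean genetic value
    ctr <- sum(d$weights * 2 * geno$snp_meta$maf[d$snp_index])
    val <- geno$dosages[, d$snp_index, drop = FALSE] %*% d$weights - ctr
    eta <- eta + d$log_or * as.vector(val)
  }
  sex <- stats::rbinom(n, 1L, 0.5)
  cohort <- sample(c("A", "B", "C"), n, replace = TRUE)
  if (truth$confound_covariates)
    eta <- eta + 0.4 * sex + 0.3 * (cohort == "B")
  status <- stats::rbinom(n, 1L, stats::plogis(eta))
  cases <- which(status == 1L); controls <- which(status == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls)
    stop(sprintf(paste0(
      "simulated cohort yielded %d cases and %d controls but %d/%d were ",
      "requested; simulate more individuals or adjust prevalence/effects"),
      length(cases), length(controls), n_cases, n_controls), call. = FALSE)
  keep <- c(sample(cases, n_cases), sample(controls, n_controls))
  pc <- matrix(stats::rnorm(length(keep) * truth$n_pcs), ncol = truth$n_pcs,
               dimnames = list(NULL, paste0("PC", seq_len(truth$n_pcs))))
  out <- data.frame(IID = geno$sample_ids[keep],
                    STATUS = status[keep], SEX = sex[keep],
                    COHORT = cohort[keep], pc, stringsAsFactors = FALSE)
  attr(out, "row_index") <- keep
  out
}

#' Marginal QTL summary statistics from a reference cohort
#'
#' Per SNP-gene pair, the simple-regression effect of effect-allele dosage on
#' standardized expression, its standard error and p-value — the shape of a
#' trans-eQTL/pQTL catalogue from an external expression GWAS.
#'
#' @param geno_ref reference-cohort `genotype_matrix` (must be disjoint from
#'   the case-control cohort; duplicated sample ids are rejected).
#' @param expression_ref matching expression matrix.
#' @param gene_meta per-gene `gene_id, chrom, tss` (defaults to the
#'   `gene_meta` attribute of `expression_ref`).
#' @return a data.frame of QTL records (`snp_id, chrom, pos, ea, oa, gene_id,
#'   gene_chrom, gene_tss, beta, se, p`). Monomorphic SNPs are skipped with a
#'   message.
#' @export
reference_summary_stats <- function(geno_ref, expression_ref,
                                    gene_meta = attr(expression_ref, "gene_meta")) {
  stopifnot(inherits(geno_ref, "genotype_matrix"))
  if (anyDuplicated(geno_ref$sample_ids))
    stop("duplicated sample ids in reference cohort; deduplicate before use",
         call. = FALSE)
  if (nrow(geno_ref$dosages) != nrow(expression_ref))
    stop("genotype and expression cohorts differ in size", call. = FALSE)
  if (is.null(gene_meta))
    stop("`gene_meta` is required (gene_id, chrom, tss)", call. = FALSE)
  n <- nrow(geno_ref$dosages)
  X <- scale(geno_ref$dosages, center = TRUE, scale = FALSE)
  ssx <- colSums(X^2)
  poly <- ssx > 0
  if (any(!poly))
    message(sprintf("skipping %d monomorphic SNP(s)", sum(!poly)))
  X <- X[, poly, drop = FALSE]; ssx <- ssx[poly]
  meta <- geno_ref$snp_meta[poly, ]
  res <- vector("list", ncol(expression_ref))
  for (g in seq_len(ncol(expression_ref))) {
    y <- as.vector(scale(expression_ref[, g]))
    xy <- as.vector(crossprod(X, y))
    beta <- xy / ssx
    ssy <- sum(y^2)
    se <- sqrt(pmax(ssy - beta^2 * ssx, 0) / ((n - 2) * ssx))
    tval <- beta / se
    gm <- gene_meta[g, ]
    res[[g]] <- data.frame(
      snp_id = meta$snp_id, chrom = meta$chrom, pos = meta$pos,
      ea = meta$ea, oa = meta$oa,
      gene_id = gm$gene_id, gene_chrom = gm$chrom, gene_tss = gm$tss,
      beta = beta, se = se, p = 2 * stats::pt(-abs(tval), n - 2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Generates, under one configuration: a reference cohort with expression and
#' its marginal QTL summary statistics (the stand-in for an external eQTL/pQTL
#' catalogue, which doubles as the LD panel), and a disjoint case-control
#' target cohort with genotypes, expression and phenotypes.
#'
#' @param config a [gate_sim_config()].
#' @param n_ref reference-cohort size.
#' @param n_cases,n_controls target-cohort composition (defaults mirror a
#'   discovery design of 5267 cases and 4909 controls).
#' @param oversample multiple of the minimal pool size simulated before
#'   rejection sampling of cases/controls.
#' @return an object of class `gate_sim`: list with `sumstats`, `geno_ref`,
#'   `expr_ref`, `geno`, `expr`, `pheno`, `truth`, `panel`, `config`.
#' @export
gate_sim <- function(config = gate_sim_config(), n_ref = 10000L,
                     n_cases = 5267L, n_controls = 4909L, oversample = 1.3) {
  panel <- make_snp_panel(config)
  truth <- .make_architecture(config, panel)
  geno_ref <- simulate_genotypes(config, n_ref, seed = config$seed + 1L,
                                 panel = panel, id_prefix = "R")
  expr_ref <- simulate_expression(geno_ref, truth, seed = config$seed + 2L)
  sumstats <- reference_summary_stats(geno_ref, expr_ref)
  n_pool <- ceiling(max(n_cases / config$prevalence,
                        n_controls / (1 - config$prevalence)) * oversample)
  geno_pool <- simulate_genotypes(config, n_pool, seed = config$seed + 3L,
                                  panel = panel, id_prefix = "T")
  pheno <- simulate_case_control(geno_pool, NULL, truth, n_cases, n_controls,
                                 seed = config$seed + 4L)
  keep <- attr(pheno, "row_index")
  geno <- subset_individuals(geno_pool, keep)
  rm(geno_pool)
  expr <- simulate_expression(geno, truth, seed = config$seed + 5L)
  attr(pheno, "row_index") <- seq_len(nrow(geno$dosages))
  structure(list(sumstats = sumstats, geno_ref = geno_ref, expr_ref = expr_ref,
                 geno = geno, expr = expr, pheno = pheno, truth = truth,
                 panel = panel, config = config),
            class = "gate_sim")
}

#' @export
print.gate_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic GATE study: %d SNPs in %d blocks; %d genes ",
    "(%d core, %d shared, %d null)\n  reference n = %d; target %d cases / %d controls\n"),
    x$config$n_snps, x$config$n_blocks, nrow(x$truth$genes),
    sum(x$truth$genes$role == "core"), sum(x$truth$genes$role == "shared"),
    sum(x$truth$genes$role == "null"),
    nrow(x$geno_ref$dosages), sum(x$pheno$STATUS == 1), sum(x$pheno$STATUS == 0)))
  invisible(x)
}
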