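#' Default pipeline configuration
#'
#' All tunable constants of the analysis in one list: simulation settings (or
#' input paths for user data), thresholds, covariates, the recurrence risk
#' ratio for the information budget, and the master seed. Any element can be
#' overridden via `...`; a YAML or JSON file path may be given instead and is
#' merged over the defaults.
#'
#' @param ... overrides of the default elements.
#' @export
gate_run_config <- function(...) {
  base <- list(
    seed = 1L,
    sim = list(n_ref = 8000L, n_cases = 2000L, n_controls = 2000L,
               n_core_genes = 3L, n_null_genes = 4L, n_shared_genes = 0L,
               prevalence = 0.1),
    paths = NULL,                 # list(sumstats=, dosages=, snp_meta=, pheno=)
    score_type = "eGATE",
    cis_window = 5e6, trans_p = 5e-8, cis_p = 1e-6,
    clump_window = 2e5, min_trans_loci = 5L, ridge = 0.1,
    hla_region = list(chrom = "6", start = 25e6, end = 34e6),
    cor_threshold = 0.25, p_core = 1e-6,
    lambda_s = 16, h2_trans = 0.4,
    run_mr = TRUE, mr = list(tau0 = 0.05, chains = 4L, iter = 2000L),
    write_genotypes = FALSE)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.character(over[[1]]))
    over <- .read_config_file(over[[1]])
  utils::modifyList(base, over)
}

.read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline into a directory
#'
#' Orchestrates simulate (or load) -> QTL catalog -> scores -> association ->
#' core-gene calls -> information -> Mendelian randomization, writing every
#' table, a locus JSON manifest and a run manifest with the configuration
#' hash. Re-running with the same configuration and seed reproduces all
#' outputs bit-identically.
#'
#' @param config a [gate_run_config()] list (or a YAML/JSON path, resolved
#'   through it).
#' @param out_dir output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the `gate` fit, the simulated study (if
#'   any), the information and MR tables, and the output paths.
#' @export
gate_run <- function(config = gate_run_config(), out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- gate_run_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop(sprintf("output directory %s is not empty", out_dir), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  hash <- .config_hash(config)

  sim <- NULL; expr <- NULL; truth <- NULL
  if (is.null(config$paths)) {
    sim_args <- config$sim
    cohort <- sim_args[intersect(names(sim_args),
                                 c("n_ref", "n_cases", "n_controls"))]
    arch <- sim_args[setdiff(names(sim_args),
                             c("n_ref", "n_cases", "n_controls"))]
    sc <- do.call(gate_sim_config, c(arch, list(seed = config$seed)))
    sim <- do.call(gate_sim, c(list(config = sc), cohort))
    sumstats <- sim$sumstats; geno <- sim$geno; pheno <- sim$pheno
    expr <- sim$expr; truth <- sim$truth
    ld_geno <- sim$geno_ref
    write_sumstats(sumstats, p("sumstats.tsv"))
    write_phenotypes(pheno, p("phenotypes.tsv"))
    if (isTRUE(config$write_genotypes))
      write_dosages(geno, p("dosages.tsv"), p("snp_meta.tsv"))
    note("simulated study under seed %d (%d SNPs, %d genes)",
         config$seed, ncol(geno$dosages), nrow(truth$genes))
  } else {
    pa <- config$paths
    sumstats <- read_sumstats(pa$sumstats)
    geno <- if (!is.null(pa$vcf)) read_genotypes_vcf(pa$vcf)
            else read_dosages(pa$dosages, pa$snp_meta)
    pheno <- read_phenotypes(pa$pheno)
    ld_geno <- geno
    note("loaded inputs from configured paths")
  }

  fit <- withCallingHandlers(
    gate(sumstats, geno, pheno, score_type = config$score_type,
         cis_window = config$cis_window, trans_p = config$trans_p,
         cis_p = config$cis_p, clump_window = config$clump_window,
         min_trans_loci = config$min_trans_loci, ridge = config$ridge,
         hla_region = config$hla_region, cor_threshold = config$cor_threshold,
         p_core = config$p_core, ld_genotypes = ld_geno),
    message = function(m) {
      note("%s", sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  note("dropped-record accounting: %s",
       paste(names(fit$catalog$counts), fit$catalog$counts,
             sep = "=", collapse = ", "))
  for (g in attr(fit$definitions, "excluded"))
    note("gene %s excluded: fewer than %d trans loci", g, config$min_trans_loci)

  tab <- summary(fit, all = TRUE)
  utils::write.table(tab, p("results.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fit$calls))
    utils::write.table(fit$calls, p("core_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_scores(fit$scores, p("scores.tsv"))
  write_locus_json(fit$definitions, p("loci.json"))

  # information-for-discrimination report for significant genes, when
  # measured expression is available (synthetic runs) and h2_trans is known
  info_tab <- NULL
  if (!is.null(fit$calls) && !is.null(expr)) {
    sig <- fit$calls[fit$calls$status != "not_significant", , drop = FALSE]
    total <- total_information(config$lambda_s)
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      gid <- sig$gene_id[i]
      if (!gid %in% colnames(expr)) return(NULL)
      sc <- fit$scores$values[, sig$score_id[i]]
      h2 <- if (!is.null(truth)) truth$genes$h2_trans[truth$genes$gene_id == gid]
            else config$h2_trans
      dil <- suppressWarnings(estimate_dilution(sc, expr[, gid], h2))
      beta <- fit$associations$log_or[fit$associations$score_id == sig$score_id[i]]
      # dilution is already clipped at 1; use the clipped r2 consistently
      est <- diluted_information(beta, max(min(dil$r2, h2), 1e-6), h2)
      data.frame(gene = gid, beta = beta, r2 = dil$r2, h2_trans = h2,
                 dilution = dil$dilution, info_bits = round(est$info_bits, 2),
                 pct_of_total = round(fraction_of_total(est$info_bits, total)),
                 stringsAsFactors = FALSE)
    })
    info_tab <- do.call(rbind, rows)
    if (!is.null(info_tab))
      utils::write.table(info_tab, p("information.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  # MR follow-up for every significant gene
  mr_tab <- NULL
  if (isTRUE(config$run_mr) && !is.null(fit$calls)) {
    sig <- fit$calls[fit$calls$status != "not_significant", , drop = FALSE]
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      inst <- extract_instruments(fit, sig$gene_id[i], geno, pheno)
      mr <- gate_mr(inst, tau0 = config$mr$tau0, chains = config$mr$chains,
                    iter = config$mr$iter, seed = config$seed + 100L + i)
      data.frame(gene = sig$gene_id[i], n_instruments = nrow(mr$wald),
                 theta = mr$theta_mean, theta_sd = mr$theta_sd,
                 ci_low = unname(mr$interval[1]), ci_high = unname(mr$interval[2]),
                 p_analog = mr$p_analog, valid = mr$valid,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    mr_tab <- do.call(rbind, rows)
    if (!is.null(mr_tab))
      utils::write.table(mr_tab, p("mr.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }

  manifest <- list(package = "gatescore",
                   version = as.character(utils::packageVersion("gatescore")),
                   r_version = R.version.string,
                   config = config, config_hash = hash,
                   counts = as.list(fit$catalog$counts))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, p("log.txt"))

  invisible(list(fit = fit, sim = sim, information = info_tab, mr = mr_tab,
                 paths = p(dir(out_dir)), config = config, hash = hash))
}
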