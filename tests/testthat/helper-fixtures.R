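# Shared fixtures, all generated in code.

# small study used by several files; memoised per test run
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- gate_sim_config(n_core_genes = 3, n_null_genes = 3,
                             n_shared_genes = 3, seed = 42,
                             hla_like_region = hla_hotspot())
      cache <<- gate_sim(cfg, n_ref = 4000, n_cases = 1500, n_controls = 1500)
    }
    cache
  }
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- small_study()
      cache <<- suppressMessages(
        gate(s$sumstats, s$geno, s$pheno, ld_genotypes = s$geno_ref))
    }
    cache
  }
})

# brute-force connected-components clumping oracle (graph connectivity over
# the pairwise within-window adjacency)
clump_oracle <- function(pos, window) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= window
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    k <- k + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (comp[v] == 0L) {
        comp[v] <- k
        stack <- c(stack, which(adj[v, ] & comp == 0L))
      }
    }
  }
  comp
}

# canonical form of a partition (set of member index sets)
partition_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}
same_partition <- function(a, b) {
  setequal(lapply(partition_sets(a), paste, collapse = ","),
           lapply(partition_sets(b), paste, collapse = ","))
}

# minimal QTL record data.frame builder
qtl_records <- function(pos, chrom = "1", gene = "G1", gene_chrom = "9",
                        gene_tss = 1e6, beta = 0.1, se = 0.01, p = 1e-10) {
  n <- length(pos)
  data.frame(snp_id = sprintf("s%03d", seq_len(n)),
             chrom = rep_len(chrom, n), pos = pos,
             ea = rep_len("A", n), oa = rep_len("G", n),
             gene_id = rep_len(gene, n), gene_chrom = rep_len(gene_chrom, n),
             gene_tss = rep_len(gene_tss, n), beta = rep_len(beta, n),
             se = rep_len(se, n), p = rep_len(p, n),
             stringsAsFactors = FALSE)
}
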