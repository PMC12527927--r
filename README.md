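# gatescore

Core-gene discovery from aggregated trans-QTL effects.

## The problem

Common variants associated with complex immune diseases are scattered across
hundreds of loci, most far from any obviously relevant gene. Under the
omnigenic/core-gene model, many of these peripheral variants act by perturbing
regulators whose effects converge — in *trans* — on a sparse set of **core
genes** in the disease-effector layer. `gatescore` implements the analysis
that exploits this: aggregate all of a gene's trans-QTLs into one polygenic
score per gene (a **GATE score**, genome-wide aggregated trans-effects),
predict the trans-regulated component of each individual's expression or
protein level from genotype alone, and test it against case-control status.

For gene *g* and individual *i*, the score is the weighted dosage sum

    S_ig = sum_j w_jg * x_ij

over the gene's clumped trans-loci, with weights obtained from marginal QTL
summary statistics by ridge LD adjustment, `w = (R + λI)⁻¹ β̂`. Trans-QTLs in
the HLA region (chr6, 25–34 Mb) are excluded and scored separately; scores
with fewer than 5 trans loci are removed; standardized scores are tested by
logistic regression adjusting for sex, cohort and principal components, so
the effect size is a log odds ratio per SD of score. Significant scores
(p < 10⁻⁶) that are not entangled in a cluster of correlated scores become
**putative core gene** calls.

Two interpretive layers follow:

* **Information for discrimination.** A standardized predictor with log OR β
  carries β²/(2·log 2) bits; the total genetic information is log₂(λs) bits
  for sibling recurrence risk ratio λs. Because a GATE score is an imperfect
  predictor of trans-regulated expression, the corrected estimate divides by
  the dilution factor r²/h²_trans:  I = β²/(2·log 2) / (r²/h²_trans).
* **Mendelian randomization.** Each trans locus is an instrument; the causal
  slope of gene product on disease is estimated while *marginalizing over
  unobserved pleiotropic instrument effects* under a horseshoe-type
  shrinkage prior, via an exact conjugate Gibbs sampler.

Everything is exercised on a built-in synthetic generator that emulates the
assumed architecture: LD-blocked genotypes, peripheral loci converging on
core genes, an interferon-signature-like block of genes sharing instruments,
an HLA-like hotspot, partial trans-heritability of expression, and a
logistic case-control disease. No external data are required.

## Worked example

```r
library(gatescore)

cfg <- gate_sim_config(n_core_genes = 3, n_null_genes = 3, n_shared_genes = 3,
                       seed = 42, hla_like_region = hla_hotspot())
sim <- gate_sim(cfg, n_ref = 4000, n_cases = 1500, n_controls = 1500)
fit <- gate(sim$sumstats, sim$geno, sim$pheno, ld_genotypes = sim$geno_ref)
fit
#> GATE analysis (eGATE): 7 score(s) tested, 6 significant at p < 1e-06,
#>   3 putative core gene(s), 3 in correlated clusters
summary(fit)
#> Candidate core genes (per-SD log OR from covariate-adjusted logistic regression)
#>  gene score_type chr tss_mb n_trans_loci log_or       p cis_log_or cis_p         status cluster
#>  G003      eGATE   3     10            6   0.33 1.8e-18       0.02  0.58  putative_core       3
#>  G002      eGATE   2     10            6   0.29 2.2e-14       0.06  0.11  putative_core       2
#>  G004      eGATE   4     10            6   0.28 1.1e-13      -0.03  0.44 cluster_member       4
#>  G006      eGATE   6     40            6   0.27 3.4e-13      -0.01  0.70 cluster_member       4
#>  G005      eGATE   5     10            5   0.27 1.4e-12       0.01  0.79 cluster_member       4
#>  G001      eGATE   1     10            6   0.26 4.3e-12       0.03  0.45  putative_core       1
```

The three configured core genes (G001–G003) are called putative core; the
three genes sharing all their trans loci (G004–G006) are significant but land
in one correlated cluster — their shared trans-effects cannot be attributed
to a single mediating gene, so none is promoted. Null genes stay
non-significant, and the HLA-like hotspot influences only the separate
HLA-specific scores (`fit$hla_associations`), never the GATE scores.

Information accounting for a score with per-SD log OR 0.23 that captures 2%
of expression variance when trans-heritability is 40%:

```r
inf <- diluted_information(beta = 0.23, r2 = 0.02, h2_trans = 0.4)
inf
#> information for discrimination: 0.76 bits (uncorrected 0.04 bits; dilution r2/h2_trans = 0.050)
fraction_of_total(inf$info_bits, total_information(16))
#> [1] 19.07964
```

— i.e. the uncorrected 0.04 bits become 0.76 bits after dilution correction,
19% of a 4-bit total genetic effect (λs = 16).

Mendelian randomization for one recovered core gene, instruments drawn from
its trans loci:

```r
inst <- extract_instruments(fit, "G001", sim$geno, sim$pheno)
gate_mr(inst, seed = 1)
#> Mendelian randomization (pleiotropy-marginalized), 6 instrument(s)
#>   causal slope: 0.410 (sd 0.072), 95% interval [0.267, 0.550]
#>   posterior tail p-analog: 0.0005
```

The whole pipeline (simulate → catalog → scores → associate → information →
MR, with every table, a locus JSON manifest, a config-hashed run manifest and
a log) runs with `gate_run(gate_run_config(seed = 1), "run1")` and is
bit-reproducible under a fixed configuration.

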