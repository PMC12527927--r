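---
title: "Aggregated trans-effects scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated trans-effects scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescore)
```

## The problem and the model

Genome-wide association studies of complex immune diseases find hundreds of
small-effect variants scattered across the genome, most of them far from any
obviously disease-relevant gene. Under the omnigenic/core-gene view, many of
these peripheral variants act by perturbing regulators whose effects converge,
in trans, on a much smaller set of *core genes* in the disease-effector layer.
If that is so, the trans-regulated component of a core gene's expression (or
protein level) should predict disease better than any single variant does.

A GATE (genome-wide aggregated trans-effects) score operationalizes this: for
one gene $g$, take all of its trans-QTLs from an external expression or
protein GWAS, and score each individual $i$ as

$$ S_{ig} = \sum_j w_{jg} \, x_{ij}, $$

where $x_{ij}$ is the effect-allele dosage and $w_{jg}$ the LD-adjusted
trans-effect of SNP $j$ on the gene's level. The score is standardized and
tested against case-control status by logistic regression with covariate
adjustment; the coefficient is the log odds ratio per SD of score. Genes
whose scores reach $p < 10^{-6}$ and are not entangled in a cluster of
correlated scores are called *putative core genes*.

## Pipeline steps and the parameters that matter

| Step | Parameter | Default | Why |
|---|---|---|---|
| cis/trans split | `cis_window` | 5 Mb | same-chromosome variants at or beyond 5 Mb from the TSS count as trans; the convention of whole-blood eQTL catalogues. Inter-chromosomal pairs are always trans. |
| trans inclusion | `trans_p` | 5e-8 | genome-wide significance for a trans-QTL to enter a score. |
| cis score | `cis_p` | 1e-6 | a cis score is reported only when at least one cis SNP passes this. |
| HLA mask | `hla_region` | chr6, 25–34 Mb (inclusive) | the HLA region is a trans-hotspot with strong direct disease effects; its trans-QTLs are excluded from GATE scores and kept as separate HLA-specific scores so that trans-aggregation is not confounded. |
| clumping | `clump_window` | 200 kb | trans-QTLs within 200 kb of each other (by single-linkage chaining) form one locus. Chaining is used because a pairwise-complete reading of "within 200 kb of each other" has no deterministic partition; chaining does, and in one dimension it is just "split at gaps > 200 kb". |
| LD adjustment | `ridge` | 0.1 | within each clump, marginal effects are converted to approximately joint effects by solving $(R + \lambda I)w = \hat\beta$ on the standardized scale, with $R$ the reference-panel correlation. $\lambda = 0$ reproduces joint OLS exactly; 0.1 stabilizes near-collinear clumps while leaving independent SNPs essentially unshrunk. |
| locus filter | `min_trans_loci` | 5 | scores built from fewer than 5 trans loci are removed: aggregation is what raises the signal-to-noise ratio, and a 1–2 locus "aggregate" is really a single-variant association in disguise. |
| covariates | `covariates` | sex, cohort, PCs | nuisance adjustment in the logistic model; a replication-style set (sex + more PCs, no cohort) is just a different column selection. |
| clustering | `cor_threshold` | 0.25 | significant scores are clustered by average-linkage on $1 - |r|$ (correlations computed in controls only) and the tree cut at height $1 - 0.25$. The threshold is not dictated by theory; 0.25 reliably separates shared-instrument blocks from independent scores in the synthetic architecture and is exposed as configuration. |
| core call | `p_core` | 1e-6 | fixed threshold, no further multiplicity correction. |

Scores are standardized on the full analysis cohort (cases + controls) before
association, so effect sizes read as per-SD log odds ratios; standardization
happens before covariate adjustment.

Clusters are computed among *detected* (significant) scores, mirroring how
correlated detected genes are reported in practice. A consequence worth
knowing: if only one member of a shared-instrument block survives the locus
filter and the significance threshold, the sharing is invisible and that
member is — correctly, per the stated rule — a putative core call.

## Information for discrimination

The total genetic contribution to a disease can be placed on an information
scale: for a rare disease with additive logistic genetic effects, the total
information for discriminating cases from non-cases equals the logarithm of
the sibling recurrence risk ratio, $\log_2 \lambda_s$ bits. A single
standardized predictor with log odds ratio $\beta$ contributes
$\beta^2/2$ nats $= \beta^2 / (2\log 2)$ bits.

A GATE score is a noisy surrogate for the trans-regulated expression
component, so its observed $\beta$ understates the underlying effect. With
$r^2$ the squared correlation between score and measured expression and
$h^2_{trans}$ the trans-heritability of expression, the corrected estimate is

$$ I = \frac{\beta^2}{2\log 2} \Big/ \frac{r^2}{h^2_{trans}}, $$

the dilution factor $r^2 / h^2_{trans}$ being the fraction of trans-heritable
variance the score captures. $h^2_{trans}$ is an external input (expression
heritability studies; the ground truth in synthetic runs), never estimated
from the case-control data. Corrected information always dominates the
uncorrected value; sampling noise can push the estimated dilution above 1, in
which case it is clipped with a warning, and estimates with $r^2 < 10^{-3}$
are flagged unstable rather than trusted.

```{r info}
total_information(16)                       # 4 bits for lambda_s = 16
fraction_of_total(0.35, total_information(16))   # a 0.35-bit pathway: 8.75%
diluted_information(beta = 0.23, r2 = 0.02, h2_trans = 0.4)
```

For a *pathway*, summing per-gene corrected estimates over correlated genes
would double-count shared trans-effects; `pathway_score()` instead combines
the member scores into one standardized predictor whose association and
dilution feed the same formula once.

## Mendelian randomization with pleiotropy marginalized

Each trans locus of a candidate gene gives an instrument: its effect on the
gene product ($\hat\beta^{exp}_j$, from the QTL study) and on disease
($\hat\beta^{out}_j$, a covariate-adjusted per-allele logistic fit). The
model is

$$ \hat\beta^{out}_j \sim \mathcal N(\theta\,\hat\beta^{exp}_j + \alpha_j,\
se^2_{out,j}), \qquad \alpha_j \sim \mathcal N(0, \tau^2\lambda_j^2), $$

with half-Cauchy priors $\lambda_j \sim C^+(0,1)$, $\tau \sim C^+(0,\tau_0)$
— a horseshoe-type global–local shrinkage prior on the direct (pleiotropic)
instrument effects. Most $\alpha_j$ are shrunk to near zero; a gross outlier
escapes shrinkage locally and stops biasing the slope. The posterior over the
causal slope $\theta$ is obtained by Gibbs sampling (the half-Cauchy scales
are expanded as inverse-gamma mixtures, making every conditional conjugate),
which is exact for this model and bit-reproducible under a seed. Exposure
betas are plugged in as fixed, standard two-sample practice; an option
inflates outcome variances by $\theta^2 se^2_{exp}$.

Defaults: $\tau_0 = 0.05$ on the log-OR scale, 4 chains of 2000 iterations
with half discarded, slope prior $\mathcal N(0, 10^2)$. Diagnostics (split
$\hat R < 1.1$, effective sample size $\ge 100$) gate a `valid` flag. The
reported "support" is a posterior tail analog,
$2\min\{P(\theta > 0), P(\theta < 0)\}$, floored at $2/n_{draws}$ — an
analog, not a frequentist p-value. With a single instrument the pleiotropy
term is unidentifiable and dropped, so the posterior concentrates on the Wald
ratio. This is the package's own fully specified Bayesian model; no claim of
equivalence to any external MR implementation is made.

## What the synthetic generator emulates — and what it does not

`gate_sim()` builds the whole study the analysis assumes:

* **Genotypes.** SNPs in LD blocks; haplotypes are latent Gaussian AR(1)
  processes (adjacent correlation `block_rho`, default 0.9) thresholded at
  the allele-frequency quantile, so dosages are marginally Binomial(2, MAF)
  with MAF drawn from \[0.05, 0.5\] (mirroring a 5% MAF filter). Note that
  thresholding attenuates correlation: latent $\rho = 0.9$ yields dosage
  correlations around 0.6–0.7 at common alleles (at most $\approx 0.71$ at
  MAF 0.5), less at rarer ones; the tests check the realized correlation
  against a numerically integrated bivariate-normal oracle.
* **Architecture.** Core genes with disjoint sets of peripheral trans loci
  (one causal SNP per block, default 8 per gene), an optional
  interferon-signature-like block of genes sharing all their trans loci,
  null genes (trans-regulated, no disease effect), per-gene cis SNPs, and an
  optional HLA-like hotspot on chr6 25–34 Mb with trans effects on every gene
  plus a direct disease effect. Effects are normalized analytically so the
  trans genetic value has variance exactly `h2_trans` (default 0.4; cis 0.1).
* **Disease.** Logistic in the standardized trans genetic values of the core
  genes (per-SD log OR `core_log_or`, default 0.3), intercept
  `qlogis(prevalence)`; exact case/control counts by rejection sampling.
  The logistic (rather than liability-threshold) form makes logistic
  regression on the true genetic value correctly specified, so
  parameter-recovery tests have an exact target. Prevalence defaults to 0.1:
  the emulated disease is uncommon, and this keeps rejection sampling of an
  oversampled case-control design tractable (a truly rare-disease prevalence
  would need millions of simulated individuals).
* **Reference cohort.** A disjoint cohort provides marginal SNP-gene
  regressions in the summary-statistic TSV dialect, and doubles as the LD
  panel for weight adjustment — the construction of the original reference
  panel is not specified, and a cohort drawn from the same population is the
  natural stand-in.
* **Study-size defaults.** `gate_sim()` defaults to 5267 cases and 4909
  controls with a 10 000-individual reference cohort, the scale of the
  discovery design it emulates. Tests and examples pass smaller sizes
  explicitly (stated where used): unit fixtures use ~3000 analysis
  individuals and 4000 reference individuals; the end-to-end recovery
  experiments use 5000/5000 with a 10 000 reference cohort, 20 replicates.

What it deliberately does **not** emulate: real LD (haplotype panels,
imputation, variable block structure), population stratification beyond
cohort labels, allele-frequency/effect-size coupling, non-Gaussian expression
noise, case-control ascertainment bias other than oversampling, X chromosome,
and measured-expression batch structure. Passing tests therefore demonstrate
the *statistical machinery* — selection, clumping, LD adjustment, score
association, clustering, calling, information correction, MR — under the
generative assumptions the analysis itself makes, not robustness to every
artifact of real cohorts.

## Numerical choices and degenerate inputs

* LD solve: base `solve()` on $(R + \lambda I)$; a singular system at
  $\lambda = 0$ raises an error instructing a positive ridge. When per-SNP
  dosage SDs are available the solve is done on the standardized scale and
  mapped back, which makes the joint-OLS identity exact with unequal SNP
  variances.
* Missing dosages: per-SNP mean imputation before summation (unbiased under
  missing-at-random); SNPs absent from the panel are skipped with a message,
  fully missing definitions dropped with a warning.
* Harmonization: allele-pair match against the panel, sign flip for swapped
  alleles, strand-ambiguous (A/T, C/G) variants dropped with a count.
* Perfect separation in a logistic fit is flagged (`flagged = TRUE`), the
  divergent estimate kept only as a sentinel; degenerate (constant)
  covariates are dropped with a message.
* Zero-variance scores are excluded from correlation matrices with a warning;
  constant scores are left centred at zero rather than divided by zero.
* Clustering ties: average linkage on $1 - |r|$ with `stats::hclust` is
  deterministic for a given matrix; no random restarts exist anywhere in the
  fit, so a `gate()` fit is a pure function of its inputs.
* All simulation seeds are small integer offsets from one master seed; every
  stochastic stage (cohorts, noise, status, MCMC) is reseeded explicitly.

## Known limitations

* The trans-QTL inclusion threshold ($5\times10^{-8}$) and the correlation
  threshold (0.25) are conventions, not estimates; both are configuration.
* The dilution correction assumes the score–expression correlation is
  entirely trans-mediated; cis contamination of the measured expression
  inflates $r^2$ and deflates the corrected information.
* Per-gene corrected information for members of a correlated cluster cannot
  be summed; use the combined pathway score.
* The MR model treats exposure effects as fixed; with weak instruments the
  optional variance inflation is a crude (not fully Bayesian) correction.
* With one detected member of a shared block, sharing is invisible (see
  above).
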