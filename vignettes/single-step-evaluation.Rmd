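---
title: "Single-step genomic evaluation and LR validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation and LR validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the animal model and its two relationship-matrix variants, the
Gibbs sampler for variance components, the LR (partial/whole) validation
estimators, and the gene-dropping simulator that makes the whole pipeline
testable without access to proprietary livestock data. It also records the
numerical and design choices that were genuinely open, and what the
simulation-based tests do and do not demonstrate.

## The model

All evaluation rests on the single-trait animal model

$$
\mathbf{y} = \mathbf{X b} + \mathbf{Z u} + \mathbf{e},\qquad
\mathbf{u} \sim N(0, \mathbf{K}\sigma^2_a),\quad
\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e),
$$

where $\mathbf{y}$ holds one record per slaughtered animal (a carcass cut
weight in kg in the motivating application), $\mathbf{b}$ contains a
slaughter-date contemporary-group effect (about 180 levels at full scale)
and a linear regression on slaughter age in days, and $\mathbf{u}$ is the
vector of additive genetic merit for *every* pedigree animal, phenotyped or
not. The relationship matrix $\mathbf{K}$ is either

* **PBLUP**: the numerator relationship matrix $\mathbf{A}$, built from the
  pedigree by the tabular method, with inbreeding ($A_{ii} = 1 + F_i$); or
* **ssGBLUP**: the single-step matrix $\mathbf{H}$, whose inverse is
  $$
  \mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & (w_G\mathbf{G} + w_A\mathbf{A}_{22})^{-1} -
  \mathbf{A}_{22}^{-1}\end{bmatrix},
  $$
  with the non-zero block on the genotyped animals, $\mathbf{A}_{22}$ the
  pedigree relationships of that subset and $\mathbf{G}$ the VanRaden
  (method 1) genomic relationship matrix
  $\mathbf{G} = \mathbf{Z}\mathbf{Z}' / (2\sum_j p_j(1-p_j))$ with
  $\mathbf{Z}$ the dosage matrix centred at twice the observed allele
  frequencies. The default blend is $w_G = 0.95$, $w_A = 0.05$, the standard
  device that keeps the genomic block invertible.

Henderson's mixed model equations are assembled sparsely (`Matrix`) and
solved by a sparse direct factorisation; the solver verifies a relative
residual below `1e-10` and applies one step of iterative refinement if
needed. $\mathbf{A}^{-1}$ is never obtained by inverting $\mathbf{A}$: it is
built directly from per-animal contributions with Mendelian-sampling
variances $d_i = 0.5 - 0.25(F_s + F_d)$ (both parents known),
$0.75 - 0.25F_p$ (one known), $1$ (founder), which is exact under
inbreeding. Fixed effects are fitted in cell-means coding (no explicit
intercept), which resolves the intercept/contemporary-group confounding;
the age covariate is centred, which affects conditioning only.

## Variance components by Gibbs sampling

`vc_gibbs()` runs a single-site Gibbs sampler: each location effect is drawn
from its Gaussian full conditional (with running residual updates, so one
sweep costs O(non-zeros)), and each variance from its scaled-inverse-
chi-square full conditional with scale $\mathbf{u}'\mathbf{K}^{-1}\mathbf{u}$
(genetic) or $\mathbf{e}'\mathbf{e}$ (residual). The default priors are flat
on the variances ($\nu = -2$, $S^2 = 0$), making posterior means comparable
to REML point estimates. The inner loop is compiled (Rcpp) but draws from
R's own RNG, so runs are exactly reproducible under `set.seed()`.

Two chain presets matter:

* desk scale, the default: 50,000 cycles, 5,000 burn-in, thinning 10
  (4,500 retained samples) — used throughout the tests and the acceptance
  script;
* full scale: 550,000 / 50,000 / 50, the published setting, available as
  `gibbs_control(chain = 550000, burn_in = 50000, thin = 50)`.

Convergence is checked by a split-chain potential scale reduction factor on
both variances (warning above 1.05) rather than visual inspection.
Summaries report $h^2$ as the posterior mean of the per-sample ratio
$\sigma^2_a/(\sigma^2_a+\sigma^2_e)$ — note that this is *not* the ratio of
the posterior means, which is why published tables of component means do not
always reproduce the published $h^2$ at two decimals — and the coefficient
of genetic variation $CV_g = 100\,\hat\sigma_a/\bar y$.

## LR validation

The LR method compares predictions for a focal cohort (here: the youngest
birth years) between a *whole* evaluation and a *partial* one in which the
focal phenotypes are masked. The package computes, per method:

* accuracy: $\hat\rho_{w,p}^2 = \widehat{\mathrm{cov}}(\hat u_w,\hat u_p) /
  \big((1+\bar F \pm 2\bar f)\,\hat\sigma^2_{u,\infty}\big)$, reported as
  the square root by default;
* bias: $\overline{\hat u_p} - \overline{\hat u_w}$ (expected 0);
* dispersion: the slope of $\hat u_w$ on $\hat u_p$ (expected 1);
* ratio estimators: the Pearson correlation between two evaluations and the
  relative gain $1/\rho - 1$, both between methods on one dataset and
  between partial and whole for one method. The whole-data accuracy is
  derived as $\hat\rho_{w,p} / \mathrm{cor}(\hat u_p, \hat u_w)$, using the
  property that this correlation estimates the ratio of partial to whole
  accuracy.

$\bar F$ is the focal cohort's mean inbreeding and $\bar f$ its mean
pairwise coancestry ($A_{ij}/2$ over distinct pairs; self-pairs belong to
$\bar F$). $\hat\sigma^2_{u,\infty}$ is the equilibrium genetic variance of
the cohort under selection, estimated from the Gibbs chain as the mean over
retained samples of the across-cohort empirical variance of the sampled
breeding values; under no selection its expectation is
$(1+\bar F-2\bar f)\sigma^2_a$, and under truncation selection it shrinks
(the Bulmer effect), which the tests verify in both directions.

Two conventions were genuinely open and are both implemented:

* the sign of $2\bar f$ in the denominator. The original derivation of the
  LR estimators uses $1+\bar F-2\bar f$, while some applied reports print
  $1+\bar F+2\bar f$. The package defaults to **minus** and stamps the
  choice into every report row (`denominator_sign`), since with small
  $\bar f$ the two differ little but silently mixing them would be worse.
* whether "accuracy" is the ratio or its square root. The ratio estimates a
  *squared* accuracy; published accuracy ranges (roughly 0.2–0.8) are most
  consistent with the square-root reading, so `sqrt_convention = TRUE` is
  the default and is likewise stamped into the report.

Negative covariances between partial and whole EBV (possible in small
cohorts) clamp the accuracy to 0 with a warning instead of crashing a
pipeline run.

## The simulator

`sim_dataset()` generates the complete study design: a multi-generation
pedigree with discrete generations and birth years; unlinked biallelic SNPs
gene-dropped from founders whose allele frequencies are uniform on
[0.05, 0.5]; a strictly additive trait controlled by a subset of the panel
(200 QTL of 5,000 SNPs by default), with effects rescaled so the founder
genetic variance is exactly $h^2\sigma^2_p$; slaughter-date effects nested
in generations; a uniform slaughter-age covariate with a small fixed slope;
and a released genotype file covering all but 5% of non-founders plus 200
founders, with 1% missingness — so phenotyped-ungenotyped,
genotyped-unphenotyped, both and neither all occur, as in real single-step
data. Optional truncation selection chooses each generation's parents among
the highest phenotypes of the previous one, simulated sequentially so
selection acts on the very records later analysed.

The default scale — 500 founders, generations of 600/600/500/300 (2,000
phenotyped), ~2,100 genotyped, focal cohort = the 300 animals of the last
birth year — mirrors the structure (though not the size) of a full
national-scale dataset of several thousand steers; it was chosen so a
complete study runs in minutes on one core while keeping the focal cohort
large enough for stable LR statistics. Replicate-based tests use a
moderately smaller configuration (250 founders, 1,150 phenotyped, 1,500
SNPs, 10 replicates) for the same reason.

What the simulator deliberately does **not** emulate: linkage and LD
structure (loci are unlinked, so marker-based accuracy here comes from
realised relationships, not LD with QTL), dominance/epistasis, genotyping
error, age structure with overlapping generations, and non-Gaussian
residuals. Passing tests therefore demonstrate that the estimators are
implemented correctly and are calibrated when the model is true; they do
not certify the accuracy levels reachable on real bovine data.

## Numerical choices and degenerate inputs

* Pedigree order is produced by Kahn's algorithm with ties broken on animal
  id, so numbering depends only on the record set, never on file row order;
  cycles and self-ancestry are hard errors naming an offending animal.
* Unknown parents are coded `0`; animals appearing only as parents are
  auto-added as founders.
* QC order is fixed: animal call rate, SNP call rate, MAF, then
  heterozygosity deviation $|H_{obs} - 2p(1-p)| > 0.15$, each on the matrix
  surviving the previous stage; the report reconciles counts by
  construction. Missing genotypes are mean-imputed (rounded $2p_j$) —
  pedigree-aware imputation is intentionally out of scope since the
  synthetic data control missingness.
* $\mathbf{G}$ may optionally be rescaled to match the mean diagonal and
  off-diagonal of $\mathbf{A}_{22}$ before blending (`tune_grm()`), as some
  single-step pipelines do; the default applies only the 0.95/0.05 blend.
* Singular $\mathbf{G}_{blend}$ or $\mathbf{A}_{22}$ abort with the matrix
  named; empty fixed-effect columns are dropped with a warning.
* $\lambda = \sigma^2_e/\sigma^2_a$ for both the whole- and the
  partial-data solves is taken from the whole-data Gibbs run, mirroring
  common LR practice of not re-estimating variances on the partial data.

## Limitations

The dense tabular $\mathbf{A}$ (and hence exact inbreeding) is quadratic in
pedigree size; it is comfortable to a few thousand animals, which is the
intended desk scale, but a million-animal evaluation would need the
Meuwissen–Luo algorithm and is out of scope. Single-trait models only;
reliabilities from the MME inverse are not computed. The equilibrium
variance estimator ties the LR denominator to the Gibbs posterior, so a
poorly converged chain propagates into the accuracy estimate — the PSRF
warning should not be ignored.
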