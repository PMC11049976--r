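---
title: "Factor-analytic genomic prediction across multi-environment trials"
author: "metGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-analytic genomic prediction across multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metGP)
```

## The problem

Wheat breeding programs evaluate candidate lines in replicated yield trials
across a set of sites (a *target population of environments*). Genotype
rankings change across sites — genotype-by-environment (G×E) interaction —
and only a subset of lines is ever grown at every site. Genomic prediction
uses genome-wide SNP markers to predict the genetic merit of lines at sites
where they were never grown, or of lines that were never grown at all.

`metGP` implements the full analysis chain: SNP panel editing, genomic
relationship matrices, a factor-analytic multi-environment mixed model
estimated by REML, BLUP prediction of genotype-within-site genetic values,
and the CV1/CV2/CV3 cross-validation designs that quantify per-site
prediction accuracy. A synthetic trial generator with known ground truth
supports calibration and testing.

## The model

For plot-level yields the model is

$$y = Xb + Z_r r + \textstyle\sum_t Z u_t + e,$$

where $b$ holds fixed site effects, $r$ random replicate-within-site effects
with per-site variances ($R = \Sigma_r \otimes I$), $e$ residuals with
per-site variances ($E = \Sigma_e \otimes I$), and each genetic term $u_t$ is
a genotype-within-site effect with separable covariance

$$\mathrm{var}(u_t) = (\Delta_t \Delta_t' + D_t) \otimes K_t .$$

The site-by-site factor $\Delta\Delta' + D$ is a factor-analytic FA($q$)
structure: $\Delta$ is a sites × $q$ loading matrix on latent environmental
factors and $D$ a diagonal of site-specific variances. The genotype-by-
genotype factor $K_t$ is a genomic kernel. The four model variants are named
by their kernels:

* **FA** — identity kernel (exchangeable genotype effects, no markers);
* **FA+G** — additive kernel
  $G_A = (X-\mu_E)(X-\mu_E)' / 2\sum_j p_j(1-p_j)$, with $\mu_{Ej} = 1-2p_j$
  the Hardy–Weinberg expectation of the $\{1,0,-1\}$ code and $p_j$ the
  minor-allele frequency;
* **FA+GG** — the first-order additive×additive epistatic kernel
  $G_A \mathbin{\#} G_A$ (elementwise square, no rescaling);
* **FA+G+GG** — both kernels, each with its own independent FA structure.

A single genotype-within-site term per kernel carries both the genetic main
effect and the G×E interaction: a factor structure with similar loadings
across sites absorbs the main effect, and splitting the two explicitly would
not be identifiable. This is the standard factor-analytic MET formulation.

Two modelling notes that users should be aware of:

* $\mu_E$ and the denominator $2\sum p(1-p)$ assume Hardy–Weinberg
  equilibrium, but inbred wheat lines are (almost) fully homozygous. The
  formula is applied as-is — the accepted practice — which makes the mean
  diagonal of $G_A$ close to 2 rather than 1 for inbred panels. Scale
  factors of this kind are absorbed by the FA variance parameters.
* FA and FA+G are *not* nested: no FA+G parameter setting reproduces
  $\Sigma \otimes I$ unless $G_A = I$. On data with genuine genomic
  structure FA+G almost always attains the higher restricted likelihood,
  but this is an empirical regularity, not an algebraic guarantee. FA+G is
  nested in FA+G+GG (switch the second term off), and the optimized
  likelihoods respect that ordering.

## REML estimation

Variances are log-parameterized (positivity), the upper triangle of the
leading $q \times q$ loading block is fixed at zero and columns carry a
positive-leading-entry sign convention (identifiability), and the specific
variances are floored at $10^{-8}$ so $\Delta\Delta'+D$ stays invertible.
Optimization is bounded L-BFGS-B with analytic gradients, started from
two-stage moment estimates (within-cell and replicate mean squares for
$\Sigma_e, \Sigma_r$; an eigendecomposition of the site covariance of
centred cell means, rescaled by the mean kernel diagonal, for $\Delta, D$)
plus seeded restarts. For two-term models one restart starts the second
term near zero, which is what makes the nested-pair likelihood ordering
hold in practice. A final polish pass with a tighter relative-change stop
removes premature terminations.

Internally the restricted likelihood is evaluated on an exact collapse of
the replicated records: whenever every observed genotype×site cell within a
site carries the same replicate labels, the likelihood factorizes into a
dense multivariate-normal REML term on the cell means (covariance
$G_{\text{cells}} + (\sigma^2_{rj}/n_j)J_{\text{site}} +
(\sigma^2_{ej}/n_j)I$) plus closed-form per-site replicate-contrast terms.
The replicate-mean and contrast subspaces are orthogonal and the fixed site
effects lie entirely in the former, so the factorization is exact; the test
suite asserts equality with the dense record-level restricted likelihood
(also exported, as `remlLoglik()`) to 10 significant digits. Designs
without within-site replicate balance fall back to numeric-gradient
optimization of the record-level likelihood, with replicate variances of
such sites pinned to zero as for single-replicate sites.

BLUPs for *every* genotype×site cell — including cells never observed —
come from the conditional mean $\hat u = C' V^{-1}(y - X\hat b)$, where the
cross-covariance $C$ runs through the kernel, so unphenotyped genotypes get
genuine marker-based predictions. Phenotypes are never imputed.

`fitFAMM()` flags `converged = TRUE` when the optimizer terminated normally
(or exhausted its iteration cap on an already-flat ridge) *and* the
projected gradient of $-2\ell_R$ is below `tol` (default 0.5 — a parameter
move of 0.01 then changes $-2\ell_R$ by at most ~0.005, far below any
practical difference). Cross-validation summaries exclude non-converged
fold fits and report the exclusion count.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `faOrder` (q) | 1 | latent factors per kernel term; must be ≤ sites. With 3–7 sites, q = 1 is usually all the data support. |
| `maxMissing` | 0.40 | drop markers with a higher missing-call fraction |
| `minMaf` | 0.05 | drop markers with a strictly lower minor-allele frequency (a marker at exactly 0.05 is retained) |
| `imputeEM` rank | 80% variance, cap 20 | rank of the low-rank EM imputation |
| `stabilizeKernel` eps | 1e-6 | diagonal ridge, added only if the minimum eigenvalue is below 1e-8 |
| `pgtol` | 1e-3 | optimizer projected-gradient stop; 0.02–0.05 is faster and accuracy-equivalent for CV work |

Marker QC applies the missingness rule before the MAF rule: allele
frequencies estimated from heavily missing markers are unreliable, so they
are removed first and frequencies are re-computed on the survivors. Both
counts are logged. Imputed dosages are left fractional; rounding back to
$\{1,0,-1\}$ would discard information that the kernel formula uses.

## Cross-validation designs

Genotypes are shuffled once under the seed and split into `nFolds`
(default 5) near-equal groups; folds are stratified by genotype only.

* **CV1** — each fold's test genotypes are masked at *all* sites:
  predicting brand-new lines.
* **CV2** — test genotypes are masked at a designated subset of sites and
  stay observed at the others: predicting lines at sites where they were
  not grown. Training data at unmasked sites include the test genotypes'
  own records. By default ⌈s/2⌉ masked sites rotate across folds;
  `maskedSites` fixes them.
* **CV3** — sparse testing: one fold keeps `nTrainFocal` genotypes
  (default 20) observed at the focal site and predicts all others there,
  with every other site fully observed. The design is parameterized by the
  explicit training count rather than a percentage, since "10% of 162"
  does not land on an integer and the canonical worked example uses 20.

Accuracy is the per-site Pearson correlation between predicted genetic
values and *observed breeding values* over the test cells, averaged across
folds (± sd across folds). "Observed breeding value" is operationalized as
the site-centred mean of a genotype's replicate yields — the usual
two-stage practice; raw means, or the simulator's true genetic values, can
be requested instead via the `observed` argument of `runCV()`. Correlations
are only reported for sites with at least 3 scored cells and nonzero
variance in both vectors. A leakage guard asserts on every fold that no
test cell's records remain in the training table.

## The synthetic trial generator

`simulateDataset()` emulates the data-generating process the analysis
assumes, with known ground truth:

* **Markers**: inbred lines; per marker a minor-allele frequency drawn
  uniformly (default 0.05–0.5), two-point $\{-1, 1\}$ genotypes with a
  small heterozygote contamination rate (default 0.02) rather than
  three-class Hardy–Weinberg sampling, plus independent missingness
  (default 10%). HWE-based centring is still applied at kernel time, as
  the formula dictates.
* **Genetic values**: explicit causal architecture — additive QTL and
  (optionally) epistatic QTL *pairs* whose products of codes enter the
  latent factor scores. Generating epistasis from marker-pair products
  rather than by sampling from $G\#G$ keeps the generative model
  independent of the analysis kernel and avoids circular validation.
  Factor scores are whitened in-sample so the genotype-level covariance of
  $\Lambda\delta_i$ is exactly $\Lambda\Lambda'$; a site-specific deviation
  with variance $\psi_j$ completes $\Lambda\Lambda' + \Psi$. That deviation
  is drawn independently of the epistatic pairs and counted with the
  additive component, so `geneticValues = additiveValues +
  epistaticValues` holds exactly. When epistatic pairs are present,
  `epiVarFrac` (default 0.3) fixes their share of factor-score variance.
* **Phenotypes**: `yield = siteMean + repEffect(site, rep) + g + e`, one
  record per genotype×site×replicate. Replicate effects are drawn once per
  (site, replicate) and shared across genotypes — exactly what the
  analysis model's $Z_r$ absorbs. Incomplete-block (alpha-lattice)
  structure is *not* simulated, because the analysis model contains no
  block term; simulating what the model cannot absorb would only inflate
  apparent residual variance.
* **Defaults** mirror a realistic South-Asian bread-wheat series: 162
  lines, 6 sites, 2 replicates, site means around 5.9 t/ha, one latent
  factor with loadings ≈ 0.28–0.48 and $\psi$ = 0.06 (between-site genetic
  correlations ≈ 0.4–0.8), replicate variance 0.04, plot residual variance
  0.2 — line-mean heritability ≈ 0.6. The trials' plot-level variance
  magnitudes are configuration defaults judged realistic for irrigated
  yield trials, not estimates of any particular dataset.
* **RNG discipline**: one stream per logical component (marker codes,
  missingness mask, genetic effects, trial noise), all derived from the
  master seed — changing `missingRate` does not perturb the genetic
  values, and identical configs give bit-identical output.

What the generator does *not* emulate: linkage/LD along chromosomes,
dominance, higher-order epistasis, year effects, incomplete blocks, and
spatial field trends. Passing tests therefore demonstrate correctness of
the estimation machinery under the model's own assumptions, not robustness
to the ways real field data violate them.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen once: kernel oracles on 3–10
genotype toys; REML oracles at 20–35 genotypes (closed form, 10×10×10 grid
search, Henderson equations); the model-hierarchy comparison at 150
genotypes × 3 sites; parameter recovery at 300 genotypes × 4 sites × 10
seeds (median elementwise genetic-correlation error ≤ 0.15); and the
qualitative cross-validation findings at 100 genotypes × 3 sites × 5 seeds
— CV2 beating CV1 by more than 0.05 mean accuracy, additive-only truth
giving FA+G and FA+G+GG accuracies within 0.05 (paired over folds where
both converged), and zero-signal accuracies within ±0.12 of zero.

## Known limitations

* Dense-matrix REML: memory and time scale with the square and cube of the
  number of observed cells; comfortable to a few thousand cells, not for
  biobank-scale panels.
* No dominance kernels, Gaussian/arc-cosine kernels, pedigree matrices,
  spatial row-column models, environmental-covariate kernels, or
  information-matrix standard errors of variance components (point
  estimates and the restricted likelihood only).
* The FA model with an identity kernel cannot predict genotypes absent
  from training (their BLUPs are exactly 0); under CV1 its accuracy is
  undefined by construction, which the harness reports as missing rather
  than as a number.

## A worked example

```{r example, eval = FALSE}
library(metGP)
sim <- simulateDataset(simConfig(nGenotypes = 100, nMarkers = 400,
                                 nSites = 3, seed = 1))
res <- runCV(sim$phenotypes, sim$markers, scheme = "CV2",
             modelNames = "FA+G", seed = 1)
res@summary
```

The same pipeline is scriptable from a shell through the thin wrapper in
`inst/scripts/metgp` (subcommands `simulate`, `qc`, `kernel`, `fit`, `cv`,
`report`), each run directory receiving a log with input checksums, the
seed and QC counts.
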