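# metGP

Factor-analytic genomic prediction for multi-environment wheat trials.

Breeding programs evaluate lines in replicated yield trials across several
sites, but no line is grown everywhere and new lines are grown nowhere.
`metGP` predicts the genetic merit of wheat lines at unobserved
genotype-by-site combinations from genome-wide SNP markers, while modelling
genotype-by-environment interaction explicitly. It is aimed at
quantitative geneticists and breeding analysts working with
multi-environment trial (MET) data.

## What it computes

The core is the mixed model for plot-level yields

    y = X b + Z_r r + sum_t Z u_t + e,
    var(u_t) = (Delta_t Delta_t' + D_t) (x) K_t

with fixed site effects `b`, random replicate-within-site effects `r`,
per-site residual variances, and one or two genotype-within-site genetic
terms whose covariance is a factor-analytic FA(q) structure over sites
(`Delta` = latent-factor loadings, `D` = site-specific variances) crossed
with a genomic kernel over genotypes. Kernels:

* additive (VanRaden): `G_A = (X - mu_E)(X - mu_E)' / (2 * sum_j p_j (1 - p_j))`
  with `mu_Ej = 1 - 2 p_j` under the `{1, 0, -1}` SNP coding;
* additive-by-additive epistatic: the Hadamard square `G_A # G_A`.

The four model variants — FA, FA+G, FA+GG, FA+G+GG — are estimated by REML
(analytic-gradient L-BFGS-B on an exact collapsed likelihood), and BLUPs of
every genotype-by-site cell are produced, including cells never observed.
Around the core sit marker QC (40% missingness / 5% MAF rules, low-rank EM
imputation), the CV1/CV2/CV3 cross-validation designs (new lines / lines
observed at some sites only / sparse testing at one focal site) with
per-site Pearson accuracies, and a synthetic MET generator with known
ground truth.

## Worked example

```r
library(metGP)
sim <- simulateDataset(simConfig(nGenotypes = 100, nMarkers = 400,
                                 nSites = 3, seed = 1))
res <- runCV(sim$phenotypes, sim$markers, scheme = "CV2",
             modelNames = "FA+G", seed = 1)
res@summary
#>   scheme model site    mean_r      sd_r n_folds_used n_folds_excluded
#> 1    CV2  FA+G   S1 0.5928032 0.1070392            3                0
#> 2    CV2  FA+G   S2 0.5657445 0.2087590            4                0
#> 3    CV2  FA+G   S3 0.4804501 0.0983178            3                0
```

Each row is one site: `mean_r` is the Pearson correlation between predicted
genetic values and observed (site-centred) line means over the test cells,
averaged across the folds in which that site was scored (under CV2 the
masked-site pair rotates, so each site is tested in 3-4 of the 5 folds),
with its across-fold standard deviation. Under CV2 the model borrows a
line's own records from unmasked sites through the factor-analytic site
covariance; rerun with `scheme = "CV1"` (brand-new lines, marker
information only) on the same data to see the characteristic drop.

A thin command-line wrapper is installed as `inst/scripts/metgp`:

```sh
Rscript inst/scripts/metgp simulate --out simdir --seed 7
Rscript inst/scripts/metgp cv --markers simdir/markers.csv \
    --phenotypes simdir/phenotypes.csv --scheme CV2 --models FA+G --out cvdir
```

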