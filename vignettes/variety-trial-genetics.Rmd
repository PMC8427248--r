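---
title: "Genetic variability analysis of multi-environment variety trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic variability analysis of multi-environment variety trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gentrial)
library(dplyr)
```

## The problem

Plant breeders evaluating advanced lines run replicated variety trials —
typically a randomized complete block design (RCBD) repeated over years or
locations — and ask three questions of every measured trait:

1. **Do the genotypes differ?** (ANOVA, mean separation)
2. **How much of the observed variation is genetic, and how much would
   selection gain?** (variance components, heritability, GCV/PCV, genetic
   advance)
3. **How do traits and genotypes relate to one another?** (correlation,
   genotype-by-trait PCA, clustering)

`gentrial` implements this pipeline end to end for balanced RCBD trials, and
ships a synthetic trial generator with *known* variance components so every
estimator in the chain can be validated by parameter recovery rather than by
faith.

## The linear model and the ANOVA

A plot observation of genotype $i$ in block $k$ of environment $j$ is modelled
additively:

$$y_{ijk} = \mu + G_i + E_j + (GE)_{ij} + B_{k(j)} + \varepsilon_{ijk}.$$

Blocks are nested within environments because complete blocks are
re-randomized in every environment. For a single environment the sources are
genotype ($g-1$ df), block ($r-1$) and error ($(g-1)(r-1)$); combined over
environments they are genotype ($g-1$), environment ($e-1$), block within
environment ($e(r-1)$), G×E ($(g-1)(e-1)$) and pooled error ($e(g-1)(r-1)$).
Balanced data use the closed-form sums of squares (verified against
`stats::aov` and against brute-force summation in the test suite); unbalanced
data are refused unless the caller opts into plot deletion
(`allow_unbalanced = TRUE`), because the method-of-moments equations below
assume balanced expected mean squares.

By default every F statistic is formed against the pooled error, which
matches how multi-environment trial reports usually print separate
$F_G$, $F_E$ and $F_{G\times E}$ columns. When environments are viewed as
random, genotype should be tested against the interaction mean square
instead; `combined_anova(..., genotype_denominator = "interaction")` does so.
A zero error mean square yields `NA` F and p values — a sentinel, never
infinity.

Means are separated with the least significant difference at level $\alpha$,

$$\mathrm{LSD} = t_{1-\alpha/2,\ \mathrm{df}_e}\sqrt{2\,\mathrm{MS}_e/n},$$

where $n$ is the number of plots behind each genotype mean ($r$ per
environment, $e\,r$ combined). The compact letter display assigns letters to
maximal runs of the descending-sorted means whose range does not exceed the
LSD, so two genotypes share a letter *iff* their means differ by at most the
LSD; ties in the sort keep input order, making the display deterministic.

## Variance components and genetic parameters

From the genotype and error mean squares of the (combined) ANOVA:

$$\hat\sigma^2_g = \frac{MS_G - MS_E}{r_\text{eff}},\qquad
  \hat\sigma^2_e = MS_E,\qquad
  \hat\sigma^2_p = \hat\sigma^2_g + \hat\sigma^2_e,$$

and from these,

$$h^2 = 100\,\frac{\sigma^2_g}{\sigma^2_p},\qquad
  \mathrm{GCV} = 100\,\frac{\sigma_g}{\mu},\qquad
  \mathrm{PCV} = 100\,\frac{\sigma_p}{\mu},$$

$$\mathrm{GA} = i\,\sigma_p\,\frac{h^2}{100},\qquad
  \mathrm{GAM} = 100\,\frac{\mathrm{GA}}{\mu},$$

with selection intensity $i = 2.06$ (selection of the top 5 %) by default.

Two conventions deserve an explicit statement:

* **Effective replication.** In a combined analysis each genotype mean
  averages $e \times r$ plots, so `genetic_summary()` defaults to
  $r_\text{eff} = e\,r$; this is the only choice that makes the magnitudes of
  combined-analysis mean squares coherent with per-trait variance components
  in the shipped reference tables. `r_effective = "per_environment"` switches
  to $r$ for users who feed per-environment mean squares.
* **Negative estimates.** Method-of-moments estimates of $\sigma^2_g$ go
  negative whenever $MS_G < MS_E$. Reported `var_g` is truncated at zero (and
  flagged), while `var_g_raw` keeps the signed value for diagnosis; the
  Monte-Carlo recovery tests use the raw value so the estimator stays
  unbiased.

The optional low/moderate/high annotation bands (10/20 % for GCV, PCV and
GAM; 30/60 % for $h^2$) are a literature convention for reading such tables,
clearly separated from the estimation itself.

## Multivariate stage

Correlation, PCA and clustering operate on the genotype-mean table, not on
plot data: published per-genotype PCA scores and the exact reproduction of
published trait correlations from printed mean tables both indicate that the
mean table is the canonical multivariate input for this kind of study.

* **Correlation**: Pearson $r$ between trait columns, with two-tailed
  p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; no multiplicity
  correction (none is customary in these reports).
* **PCA** is computed on the trait *correlation* matrix (traits standardized
  over genotypes). The eigenvalues then sum to the number of traits and each
  component explains $100\,\lambda_j/k$ percent of the variation. Loadings
  with $|\ell| > 0.3$ (strict) are flagged "important" — a conventional
  cutoff for declaring a coefficient influential. Eigenvector signs are
  arbitrary; each component is flipped so its largest-magnitude loading is
  positive, so comparisons with published tables may require a global sign
  flip per component.
* **Clustering**: UPGMA (average linkage) on Euclidean distances between
  genotype means. Traits are standardized by default, because raw Euclidean
  distance over traits measured in days, centimetres and tonnes per hectare
  is dominated by whichever trait has the largest numeric range. The
  reference study evidently clustered *raw* means (its published 3-cluster
  membership is reproduced exactly by `scale = FALSE`, and only
  approximately, with the same singleton, under standardization), so both
  modes are exposed and the flag is recorded in the result.

## The synthetic trial generator

`simulate_trial()` / `simulate_multitrait()` draw every effect of the linear
model above as an independent zero-mean Gaussian at its stated variance;
genotype effects across traits are drawn jointly through a positive
semi-definite genetic correlation matrix (eigen-based matrix square root, so
exactly singular correlation structures are accepted). One integer seed
governs the entire draw.

The default `cowpea_sim_spec()` emulates the reference cowpea trial shipped
with the package: 17 genotypes × 3 years × 3 blocks, eight maturity and yield
traits with grand means and genotypic/error variances taken from the
reference summary tables, and a genetic correlation equal to the correlation
of the published genotype means. Environment, G×E and block variances default
to zero because the reference decomposition models plot variance as genotypic
plus error only; all three can be set freely for stress-testing the combined
ANOVA.

What the generator deliberately does **not** emulate: non-Gaussian effects,
missing-data mechanisms, spatial field trends, year-specific covariates, and
heteroscedastic errors. Passing recovery tests therefore demonstrate that the
estimators are correct under the stated model — not that real field data obey
that model.

## Numerical and design choices

* Genotype, environment, block and trait labels keep **input order**
  everywhere, so output tables match field-book order reproducibly.
* Trial CSVs are written as full-precision decimal text and re-parsed with
  base R's correctly rounded `strtod`, so a write/read round trip is
  bit-exact.
* Balanced sums of squares are accumulated from cell means (asserted additive
  to the total SS at 1e-8 relative tolerance in the tests); the unbalanced
  fallback delegates to `stats::aov` after plot deletion and reports reduced
  degrees of freedom.
* `run_pipeline()` writes a manifest with package/R versions, the seed and a
  hash of the analysis-relevant configuration (the output path is excluded
  from the hash), and no timestamps — reruns with the same config and seed
  are byte-identical.
* Simulation sizes used in the shipped validation suite: 2000 replicate
  trials for variance-component recovery and 10000 for the F-test size check,
  both at the reference design (17 × 3 × 3). At these sizes the Monte-Carlo
  standard error of the mean recovered $\sigma^2_g$ is about 0.08, against a
  true value of 9.35.

## Known limitations

* Only complete-block designs; no lattice/alpha designs, spatial models or
  REML variance components.
* The printed genetic-parameter table of the reference study is internally
  rounded: recomputing its derived columns from its own printed inputs
  ($\sigma^2_g$, $\sigma^2_e$, $\mu$) reproduces $\sigma^2_p$, $h^2$, GCV and
  PCV to ±0.01 for almost every trait, but a few printed GA/GAM cells (and
  the seeds-per-pod $h^2$) disagree by up to ≈0.1 because they were evidently
  computed from unrounded intermediates — e.g. printed pods-per-plant GA and
  GAM are mutually consistent yet incompatible with the printed
  $\sigma^2_p = 54.60$ and $h^2 = 82.44$ of the same row. The package always
  computes from unrounded intermediates.
* Published per-trait F values and LSD/CV footers of the reference study are
  not recoverable without the raw plot data (which were never deposited);
  they are covered by property tests and order-of-magnitude checks on
  simulated data instead.

## A worked example

```{r example}
spec <- cowpea_sim_spec()
trial <- simulate_multitrait(trial_design(17, 3, 3, seed = 2024), spec)
genetic_summary(trial) |>
  select(trait, var_e, var_g, var_p, h2, gcv, pcv, ga, gam) |>
  mutate(across(-trait, ~ round(.x, 2)))
```

```{r example2}
ms <- mean_separation(trial, traits = "GWT")
head(ms[order(-ms$mean), ], 5)
glance(ms)
```

```{r example3}
pca <- trait_pca(genotype_means(trial))
tidy(pca, "eigenvalues")
important_traits(pca)
```
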