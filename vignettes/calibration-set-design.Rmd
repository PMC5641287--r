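---
title: "Forecasting reliability and designing calibration sets with the generalized CD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting reliability and designing calibration sets with the generalized CD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection trains a prediction model on a *calibration set* of
genotyped and phenotyped individuals, and applies it to genotyped-only
selection candidates. Two practical questions dominate its deployment in
plant breeding:

1. **Before phenotyping** — which individuals should be phenotyped so that
   the resulting predictions are as reliable as possible for a given target
   population?
2. **After training** — how reliable should the breeder expect the
   predictions of a particular target set to be?

Both questions are acute in *structured* material: nested association
mapping (NAM) designs, in which many biparental doubled-haploid (DH)
families share one central parent, concentrate their genetic variance
within families, and criteria developed for diverse panels answer the wrong
question there. What matters for selection inside a family is how well the
model resolves *within-family* differences (Mendelian sampling), not
population-wide contrasts. This package answers both questions with a
single quantity: the generalized coefficient of determination of a
contrast, evaluated with contrasts matched to the breeding objective.

## Model and criteria

### G-BLUP

Predictions come from the mixed model

$$y = X\beta + Zu + e, \qquad u \sim N(0, K\sigma_g^2), \quad
  e \sim N(0, I\sigma_e^2),$$

with $X$ an intercept by default, $Z$ the incidence of the phenotyped
records on the full individual set (calibration set plus prediction
targets), and $K$ the VanRaden genomic relationship matrix

$$K_{ij} = \frac{\sum_l (G_{il} - p_l)(G_{jl} - p_l)}{\sum_l p_l(1 - p_l)}$$

on the 0/0.5/1 dosage coding. `solve_gblup()` solves Henderson's equations
for $(\hat\beta, \hat u)$; `estimate_lambda_reml()` estimates the variance
ratio $\lambda = \sigma_e^2/\sigma_g^2$ when phenotypes are available, and
`lambda_from_h2()` converts a known heritability via
$\lambda = 1/h^2 - 1$.

### Generalized CD of a contrast

For a contrast $c$ ($1'c = 0$) over the model individuals, the expected
squared correlation between the true contrast $c'u$ and its prediction
$c'\hat u$ is

$$CD(c) = \frac{c'\left(K - \lambda\,(Z'MZ + \lambda K^{-1})^{-1}\right)c}
  {c'Kc},$$

with $M$ the projector orthogonal to the fixed-effect design. It needs
genotypes only, which is what makes it usable at design time. The related
prediction error variance is
$PEV(c) = c'(Z'MZ + \lambda K^{-1})^{-1}c \,\sigma_e^2 / c'c$, and the two
are linked by $CD(c) = 1 - \lambda\, c'(Z'MZ+\lambda K^{-1})^{-1}c / c'Kc$
— an identity the test suite verifies to $10^{-9}$ on random instances.

### Contrasts matched to the objective

* `family_mean_contrasts()` — each predicted individual against its family
  mean. Their CDs measure within-family resolution; `cdpop` (criterion
  `CDpop`) averages the *square roots* of these CDs so the criterion lives
  on the accuracy (correlation) scale.
* `population_mean_contrasts()` — each target against the mean of all
  targets, ignoring structure; `cdallnam` (`CDallNAM`) averages their root
  CDs and forecasts *global* accuracy.
* `cdpop_mean` — the unweighted mean of per-family `CDpop` values, for
  designs that must serve every family at once.
* `crit_kin()` — the mean calibration-to-target relatedness, the simple
  baseline criterion.

### Calibration-set search

`exchange_optimize()` maximizes any subset criterion by stochastic
single-swap search: a random exchange between the selected set and the
excluded pool is accepted only when it strictly improves the criterion.
`brute_force_optimize()` provides the exhaustive oracle on small pools, and
`sample_baseline()` the random and stratified (equal or size-proportional
quota) samplers.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `lambda` in OT-style design | 1 | no phenotypes exist at design time; corresponds to $h^2 = 0.5$ |
| `lambda` in prediction scenarios | from the calibration set's $h^2$ | phenotypes exist, so use their information |
| kinship ridge | $10^{-6}$ on the diagonal | internally-centered $K$ has zero row sums and is exactly singular; the ridge makes $K^{-1}$ well defined and is used consistently in CD numerator and denominator |
| MAF filter | retain $\min(p, 1-p) > 0.01$ | strict "above" rule; `maf_min = 0` disables the rule entirely |
| missingness filters | $\le 10\%$ per marker and per individual | standard array-QC thresholds for this material |
| exchange stopping | `max(10000, 100 * size)` iterations, patience 2000, 5 restarts | the search is cheap relative to criterion evaluation; restarts insure against local optima. Tests and scripts pass smaller budgets for small pools |
| REML search interval | $\lambda \in [10^{-4}, 10^4]$ | brackets heritabilities from 0.0001 to 0.9999 |

## What the simulator emulates — and what it does not

`simulate_nam()` builds DH families by crossing donor founders to one
central parent and deriving each DH line from a single F1 meiosis
(crossovers placed by Haldane's model, no interference, independence
across chromosomes) followed by genome doubling. `simulate_phenotypes()`
draws additive effects at all loci (fully polygenic by default) and sets
the residual variance from the realized breeding-value variance so the
realized $h^2$ matches its target. The end-to-end directional checks use
donor sets in which some donors are themselves offspring of crosses
between other donors, so family pairs differ genuinely in relatedness —
the feature of real multi-parental programs (founders mixing ancestral and
recent material) that gives a reliability criterion something to forecast.
Where those checks require phenotypes that follow the prediction model
exactly, they draw $u \sim N(0, K)$ directly.

The simulator does **not** reproduce: coalescent founder haplotypes or
realistic ancestral LD; marker ascertainment bias; genotyping error;
selection during DH production; non-additive architecture. Passing tests
therefore demonstrate internal consistency and the qualitative behavior of
the criteria under ideal polygenic inheritance, not performance on any real
breeding population.

## Numerical and design choices

* **Allele-frequency source.** The frequencies $p_l$ may come from an
  external reference panel or from the supplied genotype set; the default
  is the supplied set, because a matching panel often does not exist. The
  two choices give different (equally valid) relationship scales; all
  criteria are used comparatively, so the ranking of calibration sets is
  insensitive in practice. The choice is exposed, not guessed.
* **Imputation fallback.** Family-mean imputation falls back to the global
  locus mean when a whole family is missing at a locus, keeping the
  operator total.
* **Degenerate CDs.** Column CDs below $-10^{-9}$ or above $1 + 10^{-9}$
  raise an error (they indicate numerical failure); smaller excursions are
  clamped into $[0, 1]$. An empty calibration set returns CD $= 0$ exactly
  rather than relying on the $M \to 0$ limit numerically.
* **Overlapping calibration and target sets** (designs drawing the
  calibration set from the predicted population itself) need no special
  case: the model set is the union in stable input order, and `crit_kin`
  includes the self-relationship of shared ids, matching its plain
  double-mean definition.
* **Strict improvement** in the exchange search (ties rejected) prevents
  cycling on plateaus.
* **Stratified quotas** use the largest-remainder rule, with remainder ties
  spread by a seeded permutation of the families.
* **REML mechanics.** The intercept is removed by an orthonormal basis of
  its complement, the projected kinship is diagonalized once, and the
  restricted likelihood is maximized over $\log\lambda$ with Brent's
  method (tolerance $10^{-6}$); the boundary values are always compared
  against the interior candidate. A kinship numerically proportional to
  the identity makes $\sigma_g^2$ and $\sigma_e^2$ inseparable; this is
  reported as a warning with a boundary estimate.
* **Heritability pooling.** When a calibration set spans several families
  and a single $\lambda$ is needed, a `pooled` entry of the heritability
  table takes precedence; otherwise the size-weighted mean of the member
  families' $h^2$ is used, or the REML policy can be selected instead.

## Scale of the shipped checks

The package's own test battery runs at deliberately modest sizes chosen to
exercise every code path: random CD instances with up to 30 individuals;
exhaustive-search comparisons on pools of 12 candidates (495 subsets, 50
instances, 20 restarts); a 5-family × 150-DH population for the
optimization-versus-random comparison, in which each family in turn is the
prediction target (calibration sizes 30 and 60), the baseline is the mean
accuracy of 10 random sets per cell, and 10 replicate evaluations redraw
the phenotype noise; 20 replicate suites of 30 ordered family pairs for the
reliability-forecasting check; and 2000 DH for the recombination and
heritability calibrations. `scripts/acceptance.R` recomputes the same
quantities from scratch at the same sizes.

## Known limitations

* Single-trait, additive G-BLUP only; no dominance, epistasis, multi-kernel
  or group-specific-variance extensions of the CD.
* The CD forecasts *expected* reliability under the model; on real data it
  ranks prediction scenarios more faithfully than it pins their absolute
  accuracy, and its forecasts degrade when the calibration material is
  distantly related to the targets.
* The exchange search guarantees only local optimality per restart; for
  pools far larger than the shipped checks, raise `restarts` and
  `patience`.
* VCF ingestion accepts biallelic, diploid records only.
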