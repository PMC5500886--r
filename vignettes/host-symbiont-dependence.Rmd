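---
title: "Modelling host dependence on bacterial symbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host dependence on bacterial symbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the data

Hosts vary enormously in how much they depend on their bacterial symbionts:
some die without them, others barely notice their loss. Comparative tests of
what drives this variation — transmission mode, symbiont function, genome
size, age of the association — work from a compiled database of
symbiont-removal experiments: each row records host fitness measured with and
without the symbiont, how fitness was assayed, the experimental sample size,
and categorical attributes of the symbiosis (vertical vs horizontal
transmission, nutritional vs defensive function, intracellular vs
extracellular, obligate vs facultative), plus symbiont genome size (Mb) and,
where known, the age of the association (Myr).

`symbiodep` implements that analysis pipeline end to end: standardization of
heterogeneous fitness assays to a common percentage scale, phylogenetic
relatedness matrices from Newick trees, Bayesian phylogenetic mixed models
(BPMMs) fitted by a purpose-built Gibbs sampler, the derived posterior
statistics used in comparative reports, and a synthetic-data generator so the
whole chain is testable without any external data.

## Standardizing host dependence

Host dependence is quantified as the percentage drop in host fitness on
symbiont removal,

$$\mathrm{drop} = 100\,(w_{+} - w_{-})/w_{+},$$

with $w_{+}$ fitness with and $w_{-}$ without the symbiont. The drop is 100
when hosts fail completely without the symbiont, 0 when removal has no
effect, and negative (unbounded below, never clamped) when removal helps.
Because the formula presumes that larger raw values mean fitter hosts, assay
types where the opposite holds are inverted before standardization; by
default only developmental time is treated this way, controlled by the
`invert_measures` argument of `load_database()`. This orientation rule is a
package convention: source reports rarely state how "lower is better" assays
were oriented.

Observations aggregate to one record per unique host–symbiont pair; the
per-symbiosis mean drop is unweighted. Experimental sample sizes do not
weight these descriptive means — they enter the models instead, as known
per-observation measurement-error variances $1/N$ (the meta-analytic `mev`
convention).

## The model

For observation $i$ of species $s$ in study $k$,

$$y_i = x_i^\top\beta + a_s + u_s + v_k + e_i + \varepsilon_i,$$

* $x_i^\top\beta$ — fixed effects in cell-means coding (one intercept per
  factor level, no global intercept), so between-level differences are
  formed by per-iteration subtraction of level intercepts;
* $a \sim N(0, \sigma^2_p A)$ — phylogenetic effects, with $A$ the matrix of
  shared root-to-MRCA branch lengths (the Brownian-motion trait covariance);
* $u, v$ — iid species and study intercepts (multiple measures per species
  and per study);
* $e_i \sim N(0, \sigma^2_r)$ — residual;
* $\varepsilon_i \sim N(0, 1/N_i)$ — known measurement error.

In the two-trait form, fitness drop and symbiont genome size are both
Gaussian responses with trait-specific intercepts, and the phylogenetic and
residual terms carry unstructured $2\times2$ trait covariance matrices. With
a level partition (the `at.level` structure), separate phylogenetic and
residual matrices are fitted for vertically and horizontally transmitted
symbionts, each observation loading only on its own level's matrices; the
per-level trait correlations
$r = C_{12}/\sqrt{C_{11}C_{22}}$ and their per-iteration difference test
whether the drop–genome-size association depends on transmission mode.

Priors are inverse-Wishart in the $(V, \nu)$ convention of standard
animal-model software (scale $\nu V$, degrees of freedom $\nu$), default
$V = 1$, $\nu = 0.002$ — the near-flat setting used for variance components
in this literature. Fixed effects get independent $N(0, 10^{10})$ priors.
One consequence worth knowing: under this prior a *weakly identified*
correlation has most of its mass near $\pm 1$, so correlation posteriors
from small partitions should be read alongside their (wide) intervals.

## The sampler

The engine is a Gibbs sampler written for exactly this model family.
All location effects — fixed coefficients plus every random effect — are
drawn as a single joint Gaussian block from the mixed-model equations;
covariance matrices then follow from conjugate inverse-Wishart conditionals
(scale $S_0 + E^\top A^{-1} E$, degrees of freedom $\nu_0 + q$). Joint
location updates avoid the slow mixing that single-site samplers suffer when
phylogenetic effects are strongly correlated, which is why chains here can be
far shorter than the multi-million-iteration runs older software needs.

Two implementation details:

* **Residual treatment.** With one trait and one row per observation unit
  the residual effects are marginalized into the observation variance
  ($\mathrm{mev}_i + \sigma^2_r$), shrinking the joint block by one effect
  per observation; the residual variance is then updated from residual
  effects drawn from their exact conditional. With shared units across
  traits the residuals stay in the joint block as unit-level effects with a
  $2\times2$ covariance. Both paths target the same posterior.
* **Missing traits are absent rows.** Units lacking genome size contribute
  no genome-size row and nothing is imputed into the likelihood.

Numerical guards: conditional scale matrices are symmetrized and
eigenvalue-floored at $10^{-10}$; measurement-error variances are floored at
$10^{-8}$; relatedness matrices can be diagonal-jittered when zero-length
branches make them singular. Chains are reproducible: chain $c$ of a run
seeds the RNG with `seed + c - 1`, and identical seeds give bit-identical
output.

Relatedness matrices are always divided by their mean diagonal before
fitting (`scale_relatedness()`), so an ultrametric tree contributes unit
depth and the $V = 1$ prior scale means the same thing whatever tree is
supplied; outputs record this convention. Trees without branch lengths (for
example taxonomy-derived supertrees) get Grafen heights
$((d-1)/(n-1))^\rho$ with $\rho = 1$ by default.

## Posterior reporting

Every scalar quantity is summarized the same way: posterior mode of a
Gaussian-kernel density estimate (Silverman bandwidth, 512-point grid over
the sample range), 95% highest-posterior-density interval (shortest window
of the sorted draws; an equal-tailed option exists), and pMCMC — twice the
smaller fraction of draws above/below zero, floored at $2/n$ and capped at
one, with exact zeros counted in neither sign (an all-zero stream reports
1). An effect is flagged only when the HPD excludes zero *and* pMCMC < 0.05.
Phylogenetic heritability is the per-iteration percentage
$100\,\sigma^2_p/(\sigma^2_p+\sigma^2_r)$. Convergence is monitored with the
Gelman–Rubin PSRF across chains and the Geweke front-vs-back z-score
(batch-means standard errors, 20 batches — a simpler variance estimate than
spectral methods, adequate for thinned chains); analyses report results with
a prominent flag when PSRF ≥ 1.2 or |z| ≥ 2.

## The synthetic-data generator

`simulate_dataset()` draws a Yule tree (rescaled to unit height), evolves
phylogenetically clustered transmission labels down it with a symmetric
two-state Markov process, and generates drops from the same hierarchy the
model assumes — level means, phylogenetic effects with covariance
$\sigma^2_p A$ (or per-level trait covariance $\otimes A$ in two-trait
mode), species, study, residual and $N(0, 1/N)$ measurement noise — then
back-computes raw with/without fitness values so the loader reproduces the
simulated drops exactly. Biological realism constraints: fitness without
the symbiont cannot be negative, so drops above 100 are floored (the count
is recorded); genome sizes are clamped to ≥ 0.1 Mb.

Default conditions mirror the scale of the comparative literature:
vertical/horizontal mean drops 52/21 (percent), variance components
$\sigma^2_p = 400$, $\sigma^2_{sp} = 100$, $\sigma^2_{st} = 50$,
$\sigma^2_r = 100$ (so roughly 60% of species-level variance is
phylogenetic and drops span most of the 0–100 scale), 1–6 measures per
symbiosis, experimental $N$ between 5 and 50, and — in two-trait mode —
genome-size means of 1 Mb (vertical) vs 5 Mb (horizontal) with 40% of
genome sizes missing at random. The `preset_study_scale()` configuration
reproduces the dimensions of a realistic compiled database exactly: 106
symbioses, 378 fitness measures, 84 studies. What the generator does *not*
emulate: shared symbionts across hosts (tips are unique pairs), empirical
tree shape, non-Gaussian tails of real fitness data, or correlated
missingness — so passing recovery tests demonstrate correctness of the
machinery under the stated model, not robustness to violations of it.

## Problem sizes and chain lengths

The package default (`mcmc_settings()`) is a desk-scale 55,000 iterations,
5,000 burn-in, thinning 50 — 1,000 saved draws per chain, with at least 100
saved draws enforced for any reported analysis. The acceptance and test
runs use shorter chains (8,000–15,000 iterations, thinning 10–12, again ≥
1,000 saved draws) because the joint-location sampler's autocorrelation at
these model sizes is already low; recovery results at those lengths match
the longer default. Replicate-based checks use 64 species (recovery and
null calibration) and 120 species (partitioned-correlation recovery, where
per-level covariance matrices need more tips per level to be identified).

## Design choices where the ground was open

* Unknown symbiont function is kept as a third factor level, never dropped.
* Horizontal transmission implies facultative obligacy; the loader rejects
  horizontal+obligate rows, and reclassification to horizontal refuses
  obligate taxa.
* Factor levels represented by fewer than 3 symbioses are dropped (with a
  message) before single-factor analyses, mirroring replication rules used
  in comparative reports.
* Pruning preserves root-to-tip distances: when the kept taxa form a
  subclade, the stem to the old root is retained as a root edge and added
  to every entry of the relatedness matrix.
* In two-trait models the genome-size row of a symbiosis shares a residual
  unit with the first fitness observation of that pair; remaining fitness
  observations are their own units. Per-level *phylogenetic* correlations —
  the quantity of interest — do not depend on this pairing convention.
* `proportion_a_greater` in the correlation difference test uses strict
  inequality; ties count as zero.

## Limitations

Plain Gibbs with no parameter expansion mixes slowly when a variance
component is truly near zero (its chain then hugs the boundary); the
diagnostics flag this, and such components should be reported with their
full intervals, not just modes. Binary or threshold responses (for example
modelling intracellularity itself) are out of scope — responses are
Gaussian only. Model comparison statistics (DIC/WAIC) and phylogenetic
signal transforms (Pagel's λ, OU) are deliberately not provided.

## A minimal run

```r
library(symbiodep)
ds <- simulate_dataset(simulation_config(n_species = 48, seed = 1))
res <- run_analysis(analysis_plan(
  "A1_transmission", ds,
  settings = mcmc_settings(15000, 2500, 12, seed = 1, n_chains = 2)))
res$table
report(list(res))
```
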