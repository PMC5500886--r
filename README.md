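# symbiodep

Phylogenetic comparative analysis of host–symbiont dependence.

Hosts across the tree of life differ enormously in how much they depend on
their bacterial symbionts: removing an aphid's nutrient-provisioning
endosymbiont is catastrophic, while many defensive or environmentally
acquired symbionts can be lost with little cost. `symbiodep` is for
researchers compiling symbiont-removal experiments across species and asking
what predicts that variation — transmission mode (vertical vs horizontal),
symbiont function (nutritional vs defensive), genome size, age of the
association — while controlling for host and symbiont phylogeny.

The package provides the full analysis chain:

* **Standardization** — host dependence as the percentage fitness drop on
  symbiont removal, `100 (w₊ − w₋) / w₊`, computed from heterogeneous assays
  (fecundity, size/mass, survival, developmental time, resistance) with
  direction normalization for assays where lower is better; validation and
  aggregation of a tabular database to one record per unique host–symbiont
  pair.
* **Phylogenies** — Newick parsing, pruning that preserves root-to-tip
  distances, Grafen branch lengths for topology-only trees, and the
  relatedness matrix **A** of shared root-to-MRCA path lengths (Brownian
  trait covariance), scaled to unit mean diagonal.
* **Bayesian phylogenetic mixed models (BPMMs)** — a purpose-built Gibbs
  sampler for single- and two-trait Gaussian models

  `y = Xβ + a + u + v + e + ε`,

  with phylogenetic effects `a ~ N(0, σ²ₚ A)` (or 2×2 trait covariance ⊗ A),
  iid species and study intercepts, residuals, known per-observation
  measurement-error variances `mev = 1/N`, cell-means fixed effects (no
  global intercept), inverse-Wishart priors (`V = 1, nu = 0.002`), and
  transmission-specific (level-partitioned) phylogenetic and residual
  covariance matrices.
* **Posterior reporting** — kernel-density posterior mode, 95% HPD
  intervals, pMCMC, between-level differences by per-iteration subtraction,
  phylogenetic heritability `100 σ²ₚ/(σ²ₚ+σ²ᵣ)`, per-level trait correlations
  `C₁₂/√(C₁₁C₂₂)` with a difference test, Gelman–Rubin and Geweke
  diagnostics.
* **Synthetic data** — a generator producing Yule trees, phylogenetically
  clustered transmission labels, and fitness/genome data with exactly the
  variance structure the model assumes, so every stage is testable offline
  and parameter recovery can be measured against known truth.
* **Pipeline** — named analyses (transmission, function, genome size,
  transmission-specific correlations, age, localization/obligacy,
  measure-type robustness, fecundity-only subset, reclassification
  sensitivity), each runnable on the host or the symbiont phylogeny from a
  YAML config, with provenance-stamped CSV outputs.

## Worked example

Simulate a comparative data set with known truth (48 symbioses, vertical and
horizontal mean drops 52% and 21%, phylogenetic variance 400, species 100,
study 50, residual 100) and fit the transmission analysis:

```r
library(symbiodep)
ds <- simulate_dataset(simulation_config(n_species = 48, seed = 1))
res <- run_analysis(analysis_plan("A1_transmission", ds,
                                  settings = mcmc_settings(seed = 1)))
res
```

```
synthetic_dataset: 48 species;  162 observations, 48 records
symbiosis_data: 162 fitness measurements, 48 unique host-symbiont pairs, 36 studies
  transmission: horizontal=24, vertical=24
analysis_result: A1_transmission on symbiont phylogeny
                                                      name posterior_mode ci_lower ci_upper pmcmc
                                    transmissionhorizontal         25.987    0.634   48.979 0.036
                                      transmissionvertical         59.765   32.359   79.962 0.001
 difference: transmissionhorizontal - transmissionvertical        -32.194  -42.651  -20.849 0.001
                                                  V[phylo]        506.498  229.249 1150.440 0.001
                                                V[species]         53.332    0.001  147.465 0.001
                                                  V[study]         22.053    0.001   58.166 0.001
                                                  V[resid]        100.088   70.159  146.860 0.001
                                        heritability[drop]         86.017   71.895   93.955 0.001
```

Reading the table: the two transmission rows are the class mean drops (the
truth was 52 and 21; hosts of vertically transmitted symbionts lose ~60% of
fitness on removal here, hosts of horizontal ones ~26%). The `difference`
row is the posterior of the per-iteration difference between those
intercepts: −32 percentage points, 95% HPD excluding zero and pMCMC 0.001,
so vertical transmission is associated with significantly higher dependence
in this data set (generated truth: −31). `V[...]` rows are variance
components and `heritability[drop]` is the percentage of non-measurement
variance attributable to phylogeny. Each row also carries `psrf` and
`geweke_z` diagnostics (not shown); results print a prominent warning when
they exceed 1.2 / |2|.

## Command line

A thin wrapper over the same functions ships in `inst/scripts/`:

```sh
Rscript inst/scripts/symbiodep-pipeline.R generate --preset study_scale --out-dir data/
Rscript inst/scripts/symbiodep-pipeline.R run --config analysis.yml --out-dir results/
```

See `vignettes/host-symbiont-dependence.Rmd` for the model, its assumptions,
the generator's scope, and the package's design decisions.
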