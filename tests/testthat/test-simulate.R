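test_that("Yule tree simulation is binary, ultrametric and reproducible", {
  tr2 <- simulate_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(d[1], d[2])  # single cherry, tips equidistant from root
  tr <- simulate_tree(64, seed = 5)
  expect_equal(length(tr$tip.label), 64)
  expect_equal(tr$Nnode, 63)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(ape::write.tree(simulate_tree(64, seed = 5)),
                   ape::write.tree(tr))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("transmission labels follow the two-state Markov process limits", {
  tr <- simulate_tree(200, seed = 2)
  # switch rate ~ 0: all tips inherit the root state
  low <- simulate_transmission(tr, q = 1e-9, root_state = "horizontal", seed = 1)
  expect_true(all(low == "horizontal"))
  # large switch rate: tips approach independent fair draws
  high <- simulate_transmission(tr, q = 200, root_state = "vertical", seed = 1)
  expect_lt(abs(mean(high == "vertical") - 0.5), 0.1)
  expect_identical(simulate_transmission(tr, 2, seed = 3),
                   simulate_transmission(tr, 2, seed = 3))
})

test_that("with all variances off every drop equals its level mean", {
  cfg <- simulation_config(n_species = 20, var_phylo = 0, var_species = 0,
                           var_study = 0, var_resid = 0,
                           measurement_error = FALSE, seed = 4)
  ds <- simulate_dataset(cfg)
  obs <- ds$data$observations
  expect_equal(obs$fitness_drop_pct,
               unname(cfg$fixed_effects[obs$transmission]))
  expect_equal(ds$n_floored, 0)
})

test_that("synthetic data sets survive the loader round-trip unchanged", {
  ds <- simulate_dataset(simulation_config(n_species = 18, seed = 6))
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("observations.csv",
                                               "records.csv",
                                               "symbiont_tree.nwk",
                                               "truth.yml")))))
  db <- load_database(file.path(dir, "observations.csv"))
  expect_equal(db$observations$fitness_drop_pct,
               ds$data$observations$fitness_drop_pct, tolerance = 1e-9)
  expect_equal(nrow(db$records), nrow(ds$data$records))
  tr <- read_newick(file.path(dir, "symbiont_tree.nwk"))
  expect_setequal(tr$tip.label, ds$tree$tip.label)
})

test_that("latent draws decompose into the configured variance shares", {
  # GLS estimator a' A^-1 a / n is unbiased for the phylogenetic variance
  props <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_species = 200, var_phylo = 400, var_resid = 100,
                             var_species = 0, var_study = 0,
                             obs_per_species = c(1, 1),
                             measurement_error = FALSE, seed = 100 + s)
    ds <- simulate_dataset(cfg)
    A <- scale_relatedness(build_relatedness(ds$tree))
    a <- ds$latent$phylo_drop[rownames(A)]
    vp <- drop(a %*% solve(A, a)) / length(a)
    obs <- ds$data$observations
    resid <- obs$fitness_drop_pct -
      (ds$latent$level_mean + ds$latent$phylo_drop)[obs$symbiont_species]
    vr <- mean(resid^2)
    vp / (vp + vr)
  }, 1.0)
  expect_lt(abs(mean(props) - 0.8), 0.1)
})

test_that("per-level latent trait correlations match the configured truth", {
  cfg <- simulation_config(n_species = 200,
                           transmission = list(q = 4, root_state = "vertical"),
                           trait2 = trait2_config(missing_frac = 0), seed = 9)
  ds <- simulate_dataset(cfg)
  lab <- ds$latent$transmission
  for (lv in c("vertical", "horizontal")) {
    r <- cor(ds$latent$phylo_drop[lab == lv], ds$latent$phylo_genome[lab == lv])
    expect_lt(abs(r - cfg$trait2$cor_phylo[[lv]]), 0.15)
  }
})

test_that("genome sizes sit in the bacterial range with configured missingness", {
  cfg <- simulation_config(n_species = 150, trait2 = trait2_config(), seed = 10)
  ds <- simulate_dataset(cfg)
  g <- ds$data$records$genome_size
  expect_equal(mean(is.na(g)), 0.4, tolerance = 0.12)
  expect_true(all(g[!is.na(g)] >= 0.1))
})

test_that("study-scale preset reproduces the database dimensions exactly", {
  ds <- simulate_dataset(preset_study_scale(seed = 3))
  expect_equal(nrow(ds$data$records), 106)
  expect_equal(nrow(ds$data$observations), 378)
  expect_equal(length(unique(ds$data$observations$study_id)), 84)
})

test_that("recovery experiments score bias, coverage and convergence", {
  cfg <- simulation_config(n_species = 20, obs_per_species = c(1, 2), seed = 1)
  rec <- recovery_experiment(cfg, mcmc_settings(1500, 400, 10, n_chains = 2),
                             n_replicates = 2, seed = 5)
  expect_equal(nrow(rec$results), 2)
  expect_true(all(c("mode", "lower", "upper", "pmcmc", "psrf", "converged",
                    "covered") %in% names(rec$results)))
  expect_equal(rec$summary$truth, -31)
  expect_equal(rec$summary$n_replicates, 2)
  expect_lte(rec$summary$coverage, rec$summary$n_converged)
})
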