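test_that("cell-means design codes one indicator per level, no intercept", {
  d <- data.frame(y = 1:4, transmission = c("vertical", "vertical",
                                            "horizontal", "horizontal"))
  des <- construct_design(d, "transmission")
  expect_equal(des$labels, c("transmissionhorizontal", "transmissionvertical"))
  expect_equal(unname(des$X),
               matrix(c(0, 0, 1, 1, 1, 1, 0, 0), 4, 2))
  expect_true(all(rowSums(des$X) == 1))
})

test_that("covariates are centered and interactions partition the rows", {
  d <- data.frame(y = 1:6, g = rep(c("a", "b"), 3), m = rep(c("x", "y"), each = 3),
                  age = c(10, 20, 30, 40, 50, 66))
  des <- construct_design(d, "g", covariates = "age")
  expect_equal(mean(des$X[, "age"]), 0)
  des2 <- construct_design(d, c("g", "m"))
  expect_equal(ncol(des2$X), 4)
  expect_true(all(rowSums(des2$X) == 1))
  expect_error(construct_design(data.frame(y = 1, g = "a"), "g"),
               "estimability")
})

test_that("multi-response stacking keeps absent traits as absent rows", {
  t1 <- data.frame(id = c("u1", "u2", "u3"), value = c(1, 2, 3))
  t2 <- data.frame(id = c("u1", "u2", "u3"), value = c(5, NA, 7))
  long <- stack_multiresponse(t1, t2, keys = "id")
  expect_equal(nrow(long), 5)
  full <- stack_multiresponse(t1, data.frame(id = t1$id, value = 8:10),
                              keys = "id")
  expect_equal(nrow(full), 6)
  single <- stack_multiresponse(t1, NULL, keys = "id")
  expect_equal(unique(single$trait), "trait1")
  t1b <- data.frame(id = c("u1", "u2"), value = c(1, NA))
  t2b <- data.frame(id = c("u1", "u2"), value = c(5, NA))
  expect_warning(stack_multiresponse(t1b, t2b, keys = "id"), "dropped")
})

test_that("posterior of the mean matches the conjugate normal-normal oracle", {
  d <- data.frame(y = c(1, 2, 3))
  X <- matrix(1, 3, 1, dimnames = list(NULL, "mu"))
  m <- bpmm_model(d, X, fixed_resid = 1.0)
  f <- gibbs_run(m, mcmc_settings(11000, 1000, 10, seed = 42, n_chains = 1))
  b <- beta_samples(f, "mu")
  expect_length(b, 1000)
  # N(2, 1/3); 3 Monte-Carlo SEs on 1,000 draws
  expect_lt(abs(mean(b) - 2), 3 * sqrt(1 / 3 / 1000) * 1.5)
  expect_lt(abs(var(b) - 1 / 3), 3 * (1 / 3) * sqrt(2 / 999) * 1.5)
})

test_that("residual variance matches the scaled-inverse-chi-square oracle", {
  y <- withr::with_seed(7, rnorm(50, 0, 2))
  m <- bpmm_model(data.frame(y = y), X = NULL)  # coefficients fixed at zero
  f <- gibbs_run(m, mcmc_settings(11000, 1000, 10, seed = 42, n_chains = 1))
  v <- sigma_samples(f, "resid", 1, 1)
  nu0 <- 0.002
  post_df <- nu0 + 50
  post_scale <- nu0 * 1 + sum(y^2)
  an_mean <- post_scale / (post_df - 2)
  an_var <- 2 * post_scale^2 / ((post_df - 2)^2 * (post_df - 4))
  expect_lt(abs(mean(v) - an_mean), 3 * sqrt(an_var / 1000) * 2)
  expect_lt(abs(var(v) - an_var), 0.5 * an_var)
})

test_that("identical seeds give bit-identical chains", {
  cfg <- simulation_config(n_species = 16, obs_per_species = c(1, 2), seed = 3)
  ds <- simulate_dataset(cfg)
  obs <- ds$data$observations
  long <- data.frame(y = obs$fitness_drop_pct, mev = 1 / obs$sample_size,
                     species = obs$symbiont_species,
                     transmission = obs$transmission)
  A <- scale_relatedness(build_relatedness(ds$tree))
  des <- construct_design(long, "transmission")
  m <- bpmm_model(long, des$X, random = list(bpmm_term("phylo", "species", A = A)))
  s <- mcmc_settings(2000, 500, 10, seed = 9, n_chains = 1)
  f1 <- gibbs_run(m, s)
  f2 <- gibbs_run(m, s)
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[1]]$sigma, f2$chains[[1]]$sigma)
})

test_that("with negligible data weight, covariances sample from their prior", {
  # huge known measurement variance turns the posterior into the prior
  withr::with_seed(11, {
    d <- data.frame(y = rnorm(12), mev = 1e10,
                    species = sprintf("s%02d", 1:12))
    A <- diag(12); dimnames(A) <- list(d$species, d$species)
    m <- bpmm_model(d, X = NULL,
                    random = list(bpmm_term("phylo", "species", A = A,
                                            prior = prior_spec(V = 2, nu = 6))),
                    prior = prior_spec(V = 2, nu = 6))
  })
  f <- gibbs_run(m, mcmc_settings(21000, 1000, 10, seed = 5, n_chains = 1))
  # IW(nu, nu*V) scalar prior mean = nu*V/(nu-2): 12/4 = 3 (per effect level,
  # the conditional adds q = 12 effects drawn from Sigma itself; the marginal
  # of Sigma stays the prior)
  vp <- sigma_samples(f, "phylo", 1, 1)
  expect_equal(mean(vp), 3, tolerance = 0.25)
})

test_that("posterior variance of a mean contracts as species are added", {
  post_var <- vapply(c(20, 40, 80), function(n) {
    y <- withr::with_seed(n, rnorm(n, 5, 2))
    m <- bpmm_model(data.frame(y = y),
                    matrix(1, n, 1, dimnames = list(NULL, "mu")))
    f <- gibbs_run(m, mcmc_settings(6000, 1000, 5, seed = 2, n_chains = 1))
    var(beta_samples(f, "mu"))
  }, 1.0)
  expect_true(all(diff(post_var) < 0))
})

test_that("shifting one trait shifts its intercept but not the variances", {
  y <- withr::with_seed(13, rnorm(40, 10, 3))
  fit_for <- function(yv) {
    m <- bpmm_model(data.frame(y = yv),
                    matrix(1, 40, 1, dimnames = list(NULL, "mu")))
    gibbs_run(m, mcmc_settings(6000, 1000, 5, seed = 4, n_chains = 1))
  }
  f0 <- fit_for(y)
  f1 <- fit_for(y + 50)
  expect_equal(mean(beta_samples(f1, "mu")) - mean(beta_samples(f0, "mu")),
               50, tolerance = 0.5)
  expect_equal(mean(sigma_samples(f1, "resid", 1, 1)),
               mean(sigma_samples(f0, "resid", 1, 1)), tolerance = 0.15 * 9)
})

test_that("measurement-error weighting lets precise observations dominate", {
  # one discordant observation y = 5 among twenty zeros; dropping it moves
  # the posterior mean much more when it is precise (N = 100) than when it
  # is a single-replicate measurement (N = 1)
  base <- withr::with_seed(21, rnorm(20, 0, 0.1))
  fit_mean <- function(y, mev) {
    m <- bpmm_model(data.frame(y = y, mev = mev),
                    matrix(1, length(y), 1, dimnames = list(NULL, "mu")),
                    fixed_resid = 1e-4)
    mean(beta_samples(gibbs_run(m, mcmc_settings(4000, 500, 5, seed = 6,
                                                 n_chains = 1)), "mu"))
  }
  m_without <- fit_mean(base, rep(1 / 100, 20))
  m_precise <- fit_mean(c(base, 5), c(rep(1 / 100, 20), 1 / 100))
  m_noisy <- fit_mean(c(base, 5), c(rep(1 / 100, 20), 1 / 1))
  expect_gt(abs(m_precise - m_without), abs(m_noisy - m_without))
})

test_that("a single-level partition degenerates to the unpartitioned model", {
  cfg <- simulation_config(n_species = 12, obs_per_species = c(1, 1),
                           trait2 = trait2_config(missing_frac = 0),
                           seed = 8)
  ds <- simulate_dataset(cfg)
  rec <- ds$data$records
  long <- stack_multiresponse(
    data.frame(id = rec$symbiont_species, value = rec$mean_fitness_drop,
               species = rec$symbiont_species, all = "one"),
    data.frame(id = rec$symbiont_species, value = rec$genome_size,
               species = rec$symbiont_species, all = "one"),
    keys = "id", trait_names = c("drop", "genome"))
  A <- scale_relatedness(build_relatedness(ds$tree))
  X <- cbind(as.numeric(long$trait == "drop"),
             as.numeric(long$trait == "genome"))
  colnames(X) <- c("mu_drop", "mu_genome")
  m0 <- bpmm_model(long, X, random = list(bpmm_term("phylo", "species", A = A)))
  m1 <- partition_covariances(m0, "all")
  s <- mcmc_settings(2000, 500, 10, seed = 3, n_chains = 1)
  f0 <- gibbs_run(m0, s)
  f1 <- gibbs_run(m1, s)
  expect_equal(unname(f1$chains[[1]]$beta), unname(f0$chains[[1]]$beta))
  expect_equal(unname(f1$chains[[1]]$sigma[["phylo.one"]]),
               unname(f0$chains[[1]]$sigma[["phylo"]]))
})

test_that("partitioned models sample one covariance matrix per level", {
  cfg <- simulation_config(n_species = 24, obs_per_species = c(1, 1),
                           transmission = list(q = 4, root_state = "vertical"),
                           trait2 = trait2_config(missing_frac = 0), seed = 2)
  ds <- simulate_dataset(cfg)
  res <- suppressWarnings(run_analysis(analysis_plan(
    "A4_corr_by_transmission", ds,
    settings = mcmc_settings(1500, 500, 10, seed = 1, n_chains = 1))))
  expect_setequal(res$fit$term_names,
                  c("phylo.horizontal", "phylo.vertical",
                    "resid.horizontal", "resid.vertical"))
  for (tm in res$fit$term_names)
    expect_equal(dim(res$fit$chains[[1]]$sigma[[tm]])[1:2], c(2, 2))
})

test_that("saved-sample bookkeeping honours the settings contract", {
  expect_error(mcmc_settings(1000, 500, 100), "settings error")
  s <- mcmc_settings(2100, 100, 10, seed = 1, n_chains = 2)
  expect_equal(s$n_save, 200)
  m <- bpmm_model(data.frame(y = rnorm(5)),
                  matrix(1, 5, 1, dimnames = list(NULL, "mu")))
  f <- gibbs_run(m, s)
  expect_length(beta_samples(f, "mu"), 400)  # pooled over 2 chains
  expect_equal(dim(beta_samples(f, "mu", pooled = FALSE)), c(200, 2))
})
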