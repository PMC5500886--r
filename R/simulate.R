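#' Configuration of a synthetic comparative symbiosis data set
#'
#' Collects every generative parameter of the synthetic-data module: tree
#' shape, phylogenetically clustered transmission labels, group means on the
#' fitness-drop scale, variance components, an optional second (genome-size)
#' trait with per-transmission phylogenetic trait covariances, replication
#' structure and experimental sample sizes (which drive the known
#' measurement-error variances 1/N).
#'
#' Scale conventions: fitness drops are percentages (a vertical-transmission
#' mean of 52 means a 52\% drop); genome sizes are in Mb.
#'
#' @param n_species Number of symbiosis tips on the simulated tree.
#' @param birth_rate Yule birth rate.
#' @param transmission List with Markov switch rate \code{q} (per unit tree
#'   height) and \code{root_state}.
#' @param fixed_effects Named per-level means of the fitness drop (percent).
#' @param var_phylo,var_species,var_study,var_resid Variance components of the
#'   drop (percent squared).
#' @param trait2 NULL for single-trait data, or \code{trait2_config()}.
#' @param obs_per_species Integer range: measurements per symbiosis.
#' @param total_observations Optional exact total number of measurements
#'   (overrides the range; distributed over species).
#' @param sample_size_range Integer range for experimental N (mev = 1/N).
#' @param n_studies Number of studies (default about one per 4.5 measures).
#' @param measurement_error Add the Normal(0, 1/N) measurement error? (The
#'   1/N variances are recorded either way.)
#' @param func_probs Sampling probabilities of symbiont function categories.
#' @param age_fraction Fraction of symbioses with a known age.
#' @param seed Integer seed; the whole data set is reproducible from
#'   (config, seed).
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_species = 64, birth_rate = 1,
                              transmission = list(q = 2, root_state = "vertical"),
                              fixed_effects = c(vertical = 52, horizontal = 21),
                              var_phylo = 400, var_species = 100,
                              var_study = 50, var_resid = 100,
                              trait2 = NULL,
                              obs_per_species = c(1, 6),
                              total_observations = NULL,
                              sample_size_range = c(5, 50),
                              n_studies = NULL,
                              measurement_error = TRUE,
                              func_probs = c(nutritional = 0.5, defensive = 0.3,
                                             unknown = 0.2),
                              age_fraction = 0.5,
                              seed = 1) {
  stopifnot(n_species >= 2, birth_rate > 0, transmission$q > 0,
            var_phylo >= 0, var_species >= 0, var_study >= 0, var_resid >= 0,
            all(fixed_effects <= 100))
  structure(as.list(environment()), class = "simulation_config")
}

#' Second-trait (genome size) generative settings
#'
#' @param means Named per-transmission genome-size means (Mb).
#' @param var_phylo2 Named per-transmission phylogenetic variances of genome
#'   size.
#' @param cor_phylo Named per-transmission phylogenetic correlations between
#'   fitness drop and genome size (entries of the 2x2 trait covariance per
#'   transmission level).
#' @param var_resid2 Residual variance of genome size.
#' @param missing_frac Fraction of symbioses with genome size missing
#'   completely at random.
#' @return List used as the \code{trait2} field of \code{simulation_config()}.
#' @export
trait2_config <- function(means = c(vertical = 1, horizontal = 5),
                          var_phylo2 = c(vertical = 0.5, horizontal = 2),
                          cor_phylo = c(vertical = -0.6, horizontal = 0),
                          var_resid2 = 0.1, missing_frac = 0.4) {
  stopifnot(all(var_phylo2 >= 0), all(abs(cor_phylo) <= 1), var_resid2 >= 0,
            missing_frac >= 0, missing_frac < 1)
  list(means = means, var_phylo2 = var_phylo2, cor_phylo = cor_phylo,
       var_resid2 = var_resid2, missing_frac = missing_frac)
}

#' Simulate a Yule (pure-birth) tree
#'
#' Binary ultrametric tree with exponential waiting times between speciation
#' events; by default rescaled to unit root-to-tip height so that rate
#' parameters (e.g. the transmission switch rate) are per tree depth.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @param scale_height Rescale total height to 1?
#' @return An ultrametric \code{phylo} with tips sp001, sp002, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL,
                          scale_height = TRUE) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  if (scale_height) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  tree
}

#' Simulate phylogenetically clustered transmission labels
#'
#' Evolves a symmetric two-state (vertical/horizontal) continuous-time Markov
#' process from the root to the tips, so that closely related symbionts tend
#' to share a transmission mode.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param q Switch rate (per branch-length unit).
#' @param root_state State at the root.
#' @param seed Optional seed.
#' @return Named character vector of tip states.
#' @export
simulate_transmission <- function(tree, q = 2, root_state = "vertical",
                                  seed = NULL) {
  stopifnot(q > 0)
  if (!is.null(seed)) set.seed(seed)
  states <- TRANSMISSION_MODES
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  node_state <- integer(ntip + tree$Nnode)
  node_state[ntip + 1L] <- match(match.arg(root_state, states), states)
  p_flip <- 0.5 * (1 - exp(-2 * q * tree$edge.length))
  flips <- runif(nrow(tree$edge)) < p_flip
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    node_state[ch] <- if (flips[e]) 3L - node_state[par] else node_state[par]
  }
  setNames(states[node_state[seq_len(ntip)]], tree$tip.label)
}

# Draw vec(E) ~ N(0, G (x) A) and return the q x d matrix E (columns = traits).
draw_kron_normal <- function(G, A) {
  d <- nrow(G)
  q <- nrow(A)
  if (all(G == 0)) return(matrix(0, q, d))
  cg <- chol(G + diag(d) * 1e-12)
  ca <- chol(A)
  z <- matrix(rnorm(q * d), q, d)
  # chol(G (x) A) = chol(G) (x) chol(A); vec(E) = t(kron(cg, ca)) %*% z
  t(ca) %*% z %*% cg
}

#' Simulate fitness-drop (and optional genome-size) data on a tree
#'
#' Generative mirror of the analysis model: each species' latent drop is its
#' transmission-level mean plus a phylogenetic effect (covariance
#' \code{var_phylo * A}, or a per-level 2x2 trait covariance kron A when a
#' second trait is configured) plus an independent species effect; each
#' measurement adds a study effect, a residual, and a Normal(0, 1/N)
#' measurement error. Raw with/without fitness values are back-computed so
#' that the standardization formula reproduces the simulated drop exactly
#' (drops above 100 are floored by the biological constraint that fitness
#' without the symbiont cannot be negative).
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param labels Named per-tip transmission labels (from
#'   \code{simulate_transmission()}).
#' @param config A \code{simulation_config}. The RNG stream is used as-is;
#'   call via \code{simulate_dataset()} for end-to-end seeding.
#' @return Object of class \code{synthetic_dataset}: list with \code{tree},
#'   \code{host_tree} (same topology, host labels), \code{data} (a
#'   \code{symbiosis_data}), \code{truth} (the config) and \code{latent}
#'   (species-level latent values for oracle checks).
#' @export
simulate_traits <- function(tree, labels, config) {
  stopifnot(inherits(config, "simulation_config"))
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) stop("labels must cover all tips")
  trans <- labels[tips]
  n <- length(tips)
  A <- scale_relatedness(build_relatedness(tree))[tips, tips]

  # species-level latent values
  two_trait <- !is.null(config$trait2)
  phylo1 <- setNames(numeric(n), tips)
  phylo2 <- setNames(rep(NA_real_, n), tips)
  if (two_trait) {
    t2 <- config$trait2
    for (lv in unique(trans)) {
      sp <- tips[trans == lv]
      v2 <- t2$var_phylo2[[lv]]
      cv <- t2$cor_phylo[[lv]] * sqrt(config$var_phylo * v2)
      G <- matrix(c(config$var_phylo, cv, cv, v2), 2, 2)
      if (min(eigen(G, only.values = TRUE)$values) < -1e-10)
        stop("trait covariance for level '", lv, "' is not PSD")
      E <- draw_kron_normal(G, A[sp, sp, drop = FALSE])
      phylo1[sp] <- E[, 1]
      phylo2[sp] <- E[, 2]
    }
  } else if (config$var_phylo > 0) {
    phylo1[] <- drop(draw_kron_normal(matrix(config$var_phylo), A))
  }
  sp_effect <- rnorm(n, 0, sqrt(config$var_species))
  level_mean <- unname(config$fixed_effects[trans])
  if (any(is.na(level_mean)))
    stop("fixed_effects must name every transmission level present")

  # symbiont function, localization, obligacy, age (record-level attributes)
  func <- sample(names(config$func_probs), n, replace = TRUE,
                 prob = config$func_probs)
  localization <- sample(LOCALIZATIONS, n, replace = TRUE)
  obligacy <- ifelse(trans == "horizontal", "facultative",
                     sample(OBLIGACY_TYPES, n, replace = TRUE, prob = c(0.7, 0.3)))
  age <- ifelse(runif(n) < config$age_fraction, round(runif(n, 10, 300), 1),
                NA_real_)

  # replication structure
  k <- sample(seq(config$obs_per_species[1], config$obs_per_species[2]),
              n, replace = TRUE)
  if (!is.null(config$total_observations)) {
    tot <- config$total_observations
    if (tot < n) stop("total_observations must be >= n_species")
    k <- rep(floor(tot / n), n)
    extra <- tot - sum(k)
    if (extra > 0) {
      idx <- sample(n, extra)
      k[idx] <- k[idx] + 1
    }
  }
  m <- sum(k)
  n_studies <- if (is.null(config$n_studies)) max(2, round(m / 4.5)) else
    config$n_studies
  if (n_studies > m) stop("more studies than observations")
  study_of_obs <- sample(rep(seq_len(n_studies), length.out = m))  # all used
  study_effect <- rnorm(n_studies, 0, sqrt(config$var_study))

  sp_idx <- rep(seq_len(n), k)
  N <- sample(seq(config$sample_size_range[1], config$sample_size_range[2]),
              m, replace = TRUE)
  resid <- rnorm(m, 0, sqrt(config$var_resid))
  meas <- if (config$measurement_error) rnorm(m, 0, sqrt(1 / N)) else numeric(m)
  drop_val <- level_mean[sp_idx] + phylo1[sp_idx] + sp_effect[sp_idx] +
    study_effect[study_of_obs] + resid + meas

  measure_type <- sample(c("fecundity", "size_mass", "survival",
                           "developmental_time"),
                         m, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  n_floored <- sum(drop_val > 100)
  drop_val <- pmin(drop_val, 100)
  inverted <- measure_type == "developmental_time"
  fitness_with <- ifelse(inverted, 100 - drop_val, 100)
  fitness_without <- ifelse(inverted, 100, 100 - drop_val)
  # inverted assays with a full (100%) drop would give a zero baseline; nudge
  full <- inverted & fitness_with <= 0
  measure_type[full] <- "fecundity"
  fitness_with[full] <- 100
  fitness_without[full] <- 100 - drop_val[full]

  # genome size per species (trait 2)
  genome <- rep(NA_real_, n)
  if (two_trait) {
    t2 <- config$trait2
    g <- unname(t2$means[trans]) + phylo2 + rnorm(n, 0, sqrt(t2$var_resid2))
    g <- pmax(g, 0.1)
    g[runif(n) < t2$missing_frac] <- NA_real_
    genome <- g
  }

  obs <- data.frame(
    study_id = sprintf("S%03d", study_of_obs),
    host_species = paste0("host_", tips[sp_idx]),
    symbiont_species = tips[sp_idx],
    fitness_with = fitness_with,
    fitness_without = fitness_without,
    measure_type = measure_type,
    sample_size = N,
    transmission = unname(trans[sp_idx]),
    func = func[sp_idx],
    localization = localization[sp_idx],
    obligacy = obligacy[sp_idx],
    genome_size = genome[sp_idx],
    age = age[sp_idx],
    stringsAsFactors = FALSE
  )
  obs$fitness_drop_pct <- drop_val
  data <- list(observations = obs[, DB_COLUMNS], records = build_records(obs))
  class(data) <- "symbiosis_data"

  host_tree <- tree
  host_tree$tip.label <- paste0("host_", tips)

  structure(list(tree = tree, host_tree = host_tree, data = data,
                 truth = config,
                 latent = list(transmission = trans, phylo_drop = phylo1,
                               phylo_genome = phylo2, species_effect = sp_effect,
                               level_mean = setNames(level_mean, tips),
                               genome = genome),
                 n_floored = n_floored),
            class = "synthetic_dataset")
}

#' Simulate a complete synthetic data set
#'
#' Seeds the RNG from the config, simulates the tree, the transmission labels
#' (redrawn with a fresh stream if one class ends up with fewer than two
#' species) and the trait data.
#'
#' @param config A \code{simulation_config}.
#' @return A \code{synthetic_dataset}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- simulate_tree(config$n_species, config$birth_rate)
  min_class <- max(2, ceiling(0.05 * config$n_species))
  labels <- NULL
  for (try in 1:100) {
    cand <- simulate_transmission(tree, config$transmission$q,
                                  config$transmission$root_state)
    if (min(table(factor(cand, levels = TRANSMISSION_MODES))) >= min_class) {
      labels <- cand
      break
    }
  }
  if (is.null(labels))
    stop("could not draw transmission labels with both classes represented; ",
         "increase q or n_species")
  simulate_traits(tree, labels, config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$tree$tip.label), "species;")
  cat(" ", nrow(x$data$observations), "observations,",
      nrow(x$data$records), "records\n")
  print(x$data)
  invisible(x)
}

#' Study-scale synthetic preset
#'
#' A configuration whose structure mirrors the scale of the compiled
#' comparative database: 106 symbioses, exactly 378 fitness measurements
#' spread over 84 studies, vertical/horizontal mean drops of 52/21.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to \code{simulation_config()}.
#' @return A \code{simulation_config}.
#' @export
preset_study_scale <- function(seed = 1, ...) {
  args <- list(n_species = 106, total_observations = 378, n_studies = 84,
               fixed_effects = c(vertical = 52, horizontal = 21),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

#' Write a synthetic data set to disk
#'
#' Emits the observation CSV (same schema the loader reads), the record CSV,
#' both Newick trees and a truth-parameter sidecar in YAML.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_database(dataset$data, file.path(dir, "observations.csv"),
                 file.path(dir, "records.csv"))
  ape::write.tree(dataset$tree, file.path(dir, "symbiont_tree.nwk"))
  ape::write.tree(dataset$host_tree, file.path(dir, "host_tree.nwk"))
  truth <- dataset$truth
  truth$trait2 <- lapply(truth$trait2, as.list)
  yaml::write_yaml(lapply(unclass(truth), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    file.path(dir, "truth.yml"))
  invisible(dir)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a data set, fits the transmission analysis, and scores
#' how well the posterior recovers the true between-level difference in mean
#' fitness drop: bias and RMSE of posterior modes, and coverage of the 95\%
#' HPD intervals. Replicates whose chains have not converged (PSRF >= 1.2)
#' are flagged and excluded from the coverage count.
#'
#' @param config \code{simulation_config} describing the truth.
#' @param settings \code{mcmc_settings} for each fit (needs >= 2 chains for
#'   convergence flagging).
#' @param n_replicates Number of simulated replicates.
#' @param seed Base seed; replicate r simulates with seed + r - 1.
#' @return List with \code{results} (one row per replicate: posterior mode,
#'   HPD bounds, pMCMC, PSRF, convergence and coverage flags) and
#'   \code{summary} (truth, mean mode, bias, RMSE, coverage, replicate
#'   counts).
#' @export
recovery_experiment <- function(config, settings = mcmc_settings(),
                                n_replicates = 10, seed = 1) {
  stopifnot(n_replicates >= 1)
  truth <- unname(config$fixed_effects["horizontal"] -
                    config$fixed_effects["vertical"])
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed + r - 1
    ds <- simulate_dataset(cfg)
    fit_settings <- settings
    fit_settings$seed <- as.integer(seed + 1000L * r)
    res <- suppressWarnings(
      run_analysis(analysis_plan("A1_transmission", dataset = ds,
                                 settings = fit_settings)))
    tab <- res$table
    d <- tab[grepl("^difference:", tab$name), ][1, ]
    psrf <- d$psrf
    conv <- is.na(psrf) || !is.finite(psrf) || psrf < 1.2
    rows[[r]] <- data.frame(replicate = r, mode = d$posterior_mode,
                            lower = d$ci_lower, upper = d$ci_upper,
                            pmcmc = d$pmcmc, psrf = psrf, converged = conv,
                            covered = (truth >= d$ci_lower & truth <= d$ci_upper))
  }
  results <- do.call(rbind, rows)
  conv <- results$converged
  list(results = results,
       summary = list(truth = truth,
                      mean_mode = mean(results$mode),
                      bias = mean(results$mode) - truth,
                      rmse = sqrt(mean((results$mode - truth)^2)),
                      coverage = sum(results$covered & conv),
                      n_converged = sum(conv),
                      n_replicates = n_replicates))
}
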