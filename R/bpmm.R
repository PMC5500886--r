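#' MCMC chain settings
#'
#' @param n_iterations Total Gibbs iterations per chain.
#' @param burn_in Iterations discarded before saving.
#' @param thin Keep every thin-th post-burn-in iteration.
#' @param seed Integer seed; chain i uses seed + i - 1.
#' @param n_chains Number of chains (>= 2 enables Gelman-Rubin diagnostics).
#' @return List of class \code{mcmc_settings}.
#' @details The defaults (55,000 / 5,000 / 50) are a desk-scale configuration
#'   yielding 1,000 saved draws per chain; any reported analysis must keep at
#'   least 100 saved draws.
#' @export
mcmc_settings <- function(n_iterations = 55000, burn_in = 5000, thin = 50,
                          seed = 1, n_chains = 2) {
  stopifnot(n_iterations > 0, burn_in >= 0, burn_in < n_iterations,
            thin > 0, n_chains >= 1)
  n_save <- floor((n_iterations - burn_in) / thin)
  if (n_save < 100)
    stop("settings error: only ", n_save,
         " saved samples per chain; the reporting contract requires >= 100")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), n_chains = as.integer(n_chains),
                 n_save = as.integer(n_save)),
            class = "mcmc_settings")
}

#' Inverse-Wishart prior specification
#'
#' Priors follow the (V, nu) convention of standard animal-model software: the
#' inverse-Wishart has degrees of freedom \code{nu} and scale matrix
#' \code{nu * V}, so \code{V = 1, nu = 0.002} is a near-flat variance prior.
#'
#' @param V Prior (co)variance scale: scalar (expanded to a diagonal matrix of
#'   the trait dimension) or matrix.
#' @param nu Degree-of-belief parameter.
#' @param v_beta Prior variance of each fixed-effect coefficient
#'   (default effectively flat).
#' @return List of class \code{prior_spec}.
#' @export
prior_spec <- function(V = 1, nu = 0.002, v_beta = 1e10) {
  stopifnot(nu > 0, v_beta > 0)
  structure(list(V = V, nu = nu, v_beta = v_beta), class = "prior_spec")
}

#' Random-effect term of a phylogenetic mixed model
#'
#' @param name Term label used in outputs (e.g. \code{"phylo"}).
#' @param group Column of the model data giving the grouping factor (e.g.
#'   species).
#' @param A Optional relatedness matrix with taxon dimnames covering all group
#'   levels; omitted = iid effects.
#' @param partition Optional column name: fit a separate covariance matrix per
#'   level of this attribute, with each group level loading only on its own
#'   level's matrix (the at.level structure used for transmission-specific
#'   covariances).
#' @param fixed Optional fixed value (scalar or matrix) for this term's
#'   covariance matrix: it is then not sampled (testing hook).
#' @param prior Optional \code{prior_spec} overriding the model prior.
#' @param jitter Diagonal jitter added to A before inversion (guards against
#'   singular matrices from zero-length branches).
#' @return List of class \code{bpmm_term}.
#' @export
bpmm_term <- function(name, group, A = NULL, partition = NULL, fixed = NULL,
                      prior = NULL, jitter = 0) {
  structure(list(name = name, group = group, A = A, partition = partition,
                 fixed = fixed, prior = prior, jitter = jitter),
            class = "bpmm_term")
}

#' Cell-means fixed-effect design matrix
#'
#' Builds the fixed design with no global intercept: one indicator column per
#' observed level of the primary factor (so each level's mean is estimated
#' directly and between-level differences can be formed by per-iteration
#' subtraction), plus optional treatment-contrast columns for extra factors
#' and optional centered continuous covariates. With multiple traits every
#' column is trait-specific, so each trait's intercepts are estimated
#' separately.
#'
#' @param data Long-format model data (columns \code{trait} plus the factor /
#'   covariate columns referenced).
#' @param primary Column name(s) of the primary factor (a vector = their
#'   interaction).
#' @param extras Optional extra factor columns, contrast-coded against their
#'   first observed level.
#' @param covariates Optional numeric columns entered as slopes.
#' @param center Center covariates (per trait) before entry?
#' @return List with \code{X} (observation x coefficient matrix) and
#'   \code{labels}; \code{primary_levels} maps traits to their level labels.
#' @export
construct_design <- function(data, primary, extras = NULL, covariates = NULL,
                             center = TRUE) {
  if (!("trait" %in% names(data))) data$trait <- "trait1"
  traits <- unique(data$trait)
  M <- nrow(data)
  cols <- list()
  primary_levels <- list()
  for (tr in traits) {
    rows <- which(data$trait == tr)
    pref <- if (length(traits) > 1) paste0(tr, ":") else ""
    fvals <- do.call(interaction, c(lapply(primary, function(p) {
      if (!(p %in% names(data))) stop("unknown design field: ", p)
      data[[p]][rows]
    }), drop = TRUE, sep = "."))
    levs <- levels(fvals)
    if (length(levs) < 2)
      stop("estimability error: factor '", paste(primary, collapse = ":"),
           "' has fewer than 2 observed levels for trait ", tr)
    for (l in levs) {
      v <- numeric(M)
      v[rows[fvals == l]] <- 1
      cols[[paste0(pref, paste(primary, collapse = ":"), l)]] <- v
    }
    primary_levels[[tr]] <- paste0(pref, paste(primary, collapse = ":"), levs)
    for (ex in extras) {
      if (!(ex %in% names(data))) stop("unknown design field: ", ex)
      evals <- data[[ex]][rows]
      elevs <- sort(unique(evals))
      if (length(elevs) < 2)
        stop("estimability error: factor '", ex,
             "' has fewer than 2 observed levels for trait ", tr)
      for (l in elevs[-1]) {
        v <- numeric(M)
        v[rows[evals == l]] <- 1
        cols[[paste0(pref, ex, l)]] <- v
      }
    }
    for (cv in covariates) {
      if (!(cv %in% names(data))) stop("unknown design field: ", cv)
      vals <- data[[cv]][rows]
      if (any(is.na(vals)))
        stop("covariate '", cv, "' has missing values on trait ", tr, " rows")
      if (center) vals <- vals - mean(vals)
      v <- numeric(M)
      v[rows] <- vals
      cols[[paste0(pref, cv)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  zero <- colSums(abs(X)) == 0
  if (any(zero))
    stop("collinear (all-zero) design column: ",
         paste(colnames(X)[zero], collapse = ", "))
  list(X = X, labels = colnames(X), primary_levels = primary_levels)
}

#' Stack two trait tables into one long multi-response table
#'
#' Units missing a trait simply contribute no row for it (no imputation);
#' units with neither trait are dropped with a warning.
#'
#' @param tab1,tab2 data.frames each containing the key columns, a
#'   \code{value} column, optionally \code{mev}, and any shared attribute
#'   columns. \code{tab2} may be NULL or empty (degenerates to single
#'   response).
#' @param keys Columns identifying the observation unit.
#' @param trait_names Labels for the two traits.
#' @return Long data.frame with columns \code{trait}, \code{y}, \code{unit},
#'   \code{mev} and all key/attribute columns.
#' @export
stack_multiresponse <- function(tab1, tab2 = NULL, keys,
                                trait_names = c("trait1", "trait2")) {
  prep <- function(tab, nm) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    if (!("value" %in% names(tab))) stop("table lacks a 'value' column")
    tab <- tab[!is.na(tab$value), , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    tab$trait <- nm
    tab$y <- tab$value
    if (!("mev" %in% names(tab))) tab$mev <- 0
    tab$unit <- do.call(paste, c(tab[keys], sep = "\r"))
    tab
  }
  t1 <- prep(tab1, trait_names[1])
  t2 <- prep(tab2, trait_names[2])
  if (is.null(t1) && is.null(t2)) stop("no trait values to stack")
  common <- if (is.null(t2)) names(t1) else intersect(names(t1), names(t2))
  out <- rbind(if (!is.null(t1)) t1[common] else NULL,
               if (!is.null(t2)) t2[common] else NULL)
  all_units <- unique(c(if (!is.null(tab1)) do.call(paste, c(tab1[keys], sep = "\r")),
                        if (!is.null(tab2) && nrow(tab2) > 0)
                          do.call(paste, c(tab2[keys], sep = "\r"))))
  dropped <- setdiff(all_units, out$unit)
  if (length(dropped) > 0)
    warning(length(dropped), " unit(s) with neither trait observed were dropped")
  rownames(out) <- NULL
  out
}

#' Specify a Bayesian phylogenetic mixed model
#'
#' Assembles the data, fixed design, random terms (with optional relatedness
#' matrices and level partitions), per-observation measurement-error variances
#' and priors into a ready-to-sample model.
#'
#' @param data Long-format data.frame with columns \code{y}, optionally
#'   \code{trait} (multi-response), \code{unit} (observation unit for the
#'   residual term; defaults to one unit per row), \code{mev} (known
#'   measurement-error variance per row, e.g. 1/N; defaults to 0), plus all
#'   grouping/partition columns used by the terms.
#' @param X Fixed design matrix from \code{construct_design()} (or NULL for a
#'   model with no fixed effects, i.e. coefficients fixed at zero).
#' @param random List of \code{bpmm_term()} objects.
#' @param resid_partition Optional column name: separate residual covariance
#'   matrix per level of this attribute.
#' @param fixed_resid Optional fixed residual covariance (testing hook).
#' @param prior \code{prior_spec()} defaults for all terms.
#' @param mev_floor Lower floor applied to measurement-error variances so the
#'   observation noise is never exactly degenerate.
#' @return Object of class \code{bpmm_model}.
#' @export
bpmm_model <- function(data, X, random = list(), resid_partition = NULL,
                       fixed_resid = NULL, prior = prior_spec(),
                       mev_floor = 1e-8) {
  stopifnot(is.data.frame(data), "y" %in% names(data))
  if (!("trait" %in% names(data))) data$trait <- "trait1"
  if (!("unit" %in% names(data))) data$unit <- paste0("u", seq_len(nrow(data)))
  if (!("mev" %in% names(data))) data$mev <- 0
  if (any(!is.finite(data$y))) stop("non-finite response values")
  traits <- unique(data$trait)
  nt <- length(traits)
  if (anyDuplicated(paste(data$unit, data$trait, sep = "\r")))
    stop("each unit may contribute at most one row per trait")

  if (is.list(X)) X <- X$X
  p_fixed <- if (is.null(X)) 0L else ncol(X)
  if (p_fixed > 0 && nrow(X) != nrow(data))
    stop("design matrix rows must match data rows")

  # Residual treatment: with a single trait and one row per unit the
  # unit-level residual effects are marginalized into the observation
  # variance (smaller joint location block, same posterior); otherwise they
  # are explicit unit-level random effects.
  marg <- nt == 1 && !anyDuplicated(data$unit)
  resid_term <- bpmm_term("resid", group = "unit", partition = resid_partition,
                          fixed = fixed_resid)
  terms <- if (marg) random else c(random, list(resid_term))

  resid_info <- NULL
  if (marg) {
    rl <- if (is.null(resid_partition)) rep("", nrow(data)) else
      as.character(data[[resid_partition]])
    levels <- sort(unique(rl))
    Vr <- if (length(prior$V) == 1) prior$V else prior$V[1, 1]
    counts <- table(factor(rl, levels = levels))
    if (!is.null(resid_partition) && any(counts < 3))
      warning("residual partition level(s) with fewer than 3 units: ",
              paste(levels[counts < 3], collapse = ", "))
    fixed_val <- fixed_resid
    if (!is.null(fixed_val)) fixed_val <- as.numeric(fixed_val)[1]
    resid_info <- list(levels = levels,
                       level_index = match(rl, levels) - 1L,
                       n_levels = length(levels),
                       S0 = rep(prior$nu * Vr, length(levels)),
                       nu0 = prior$nu,
                       fixed = !is.null(fixed_val),
                       sigma0 = rep(if (is.null(fixed_val)) 1 else fixed_val,
                                    length(levels)))
  }

  built <- list()
  offset <- p_fixed
  for (tm in terms) {
    if (!(tm$group %in% names(data))) stop("unknown grouping column: ", tm$group)
    pr <- if (is.null(tm$prior)) prior else tm$prior
    V <- pr$V
    if (length(V) == 1) V <- diag(nt) * V
    if (!all(dim(V) == nt)) stop("prior V dimension must match trait dimension")
    S0 <- pr$nu * V
    part_col <- tm$partition
    if (!is.null(part_col) && !(part_col %in% names(data)))
      stop("unknown partition column: ", part_col)
    part_levels <- if (is.null(part_col)) "" else sort(unique(data[[part_col]]))
    for (pl in part_levels) {
      rows <- if (is.null(part_col)) seq_len(nrow(data)) else
        which(data[[part_col]] == pl)
      groups <- unique(data[[tm$group]][rows])
      if (!is.null(part_col)) {
        # a group level must belong to exactly one partition level
        other <- data[[tm$group]][-rows]
        if (any(groups %in% other))
          stop("group '", tm$group, "' level(s) span multiple '", part_col,
               "' levels: ", paste(intersect(groups, other)[1], collapse = ", "))
        if (length(groups) < 3)
          warning("partition level '", pl, "' of term '", tm$name,
                  "' has fewer than 3 group levels; estimates may be poor")
      }
      if (!is.null(tm$A)) {
        taxa <- rownames(tm$A)
        miss <- setdiff(groups, taxa)
        if (length(miss) > 0)
          stop("term '", tm$name, "': group levels missing from relatedness ",
               "matrix: ", paste(miss, collapse = ", "))
        groups <- taxa[taxa %in% groups]  # taxon-order contract
        Ainv <- invert_relatedness(tm$A[groups, groups, drop = FALSE], tm$jitter)
      } else {
        Ainv <- diag(length(groups))
      }
      fixed_val <- tm$fixed
      if (!is.null(fixed_val)) {
        if (length(fixed_val) == 1) fixed_val <- diag(nt) * fixed_val
        fixed_val <- as.matrix(fixed_val)
      }
      q <- length(groups)
      label <- if (nzchar(pl)) paste(tm$name, pl, sep = ".") else tm$name
      built[[label]] <- list(
        name = label, base = tm$name, level = pl, group = tm$group,
        offset = offset, q = q, d = nt, groups = groups,
        iid = is.null(tm$A),
        Ainv = Ainv, S0 = S0, nu0 = pr$nu,
        fixed = !is.null(fixed_val),
        Sigma = if (!is.null(fixed_val)) fixed_val else diag(nt),
        rows = rows)
      offset <- offset + q * nt
    }
  }

  # sparse location design W = [X | Z_term1 | Z_term2 | ...] in triplet form
  M <- nrow(data)
  trait_idx <- match(data$trait, traits)
  tri_r <- integer(0); tri_c <- integer(0); tri_v <- numeric(0)
  if (p_fixed > 0) {
    nz <- which(X != 0, arr.ind = TRUE)
    tri_r <- nz[, 1]; tri_c <- nz[, 2]; tri_v <- X[nz]
  }
  for (bt in built) {
    g_idx <- match(data[[bt$group]][bt$rows], bt$groups)
    tri_r <- c(tri_r, bt$rows)
    tri_c <- c(tri_c, bt$offset + (trait_idx[bt$rows] - 1L) * bt$q + g_idx)
    tri_v <- c(tri_v, rep(1, length(bt$rows)))
  }
  ord <- order(tri_r)
  tri_r <- tri_r[ord]; tri_c <- tri_c[ord]; tri_v <- tri_v[ord]
  w_ptr <- c(0L, cumsum(tabulate(tri_r, nbins = M)))

  structure(list(data = data, X = X, p_fixed = p_fixed,
                 w_ptr = as.integer(w_ptr), w_idx = as.integer(tri_c - 1L),
                 w_val = tri_v, p_theta = offset, resid_info = resid_info,
                 labels = if (p_fixed > 0) colnames(X) else character(0),
                 traits = traits, terms = built, prior = prior,
                 dvar = pmax(data$mev, mev_floor), random = random,
                 resid_partition = resid_partition, fixed_resid = fixed_resid,
                 mev_floor = mev_floor),
            class = "bpmm_model")
}

#' Duplicate covariance matrices per level of an attribute
#'
#' Rebuilds a model so that every phylogenetic (relatedness-structured) term
#' and the residual term get a separate covariance matrix per level of
#' \code{attribute}, with each observation loading only on its own level's
#' matrices. A single-level attribute degenerates to the unpartitioned model.
#'
#' @param model A \code{bpmm_model}.
#' @param attribute Column of the model data to partition on.
#' @return The re-specified \code{bpmm_model}.
#' @export
partition_covariances <- function(model, attribute) {
  stopifnot(inherits(model, "bpmm_model"))
  if (!(attribute %in% names(model$data)))
    stop("unknown partition column: ", attribute)
  random <- lapply(model$random, function(tm) {
    if (!is.null(tm$A)) tm$partition <- attribute
    tm
  })
  bpmm_model(model$data, model$X, random = random,
             resid_partition = attribute, fixed_resid = model$fixed_resid,
             prior = model$prior, mev_floor = model$mev_floor)
}

#' Run the Gibbs sampler
#'
#' Samples the posterior of a Gaussian phylogenetic mixed model. All location
#' effects (fixed coefficients plus every random effect, including unit-level
#' residual effects) are drawn as one joint Gaussian block from the
#' mixed-model equations; each covariance matrix is then drawn from its
#' conjugate inverse-Wishart conditional. Identical seeds give bit-identical
#' chains.
#'
#' @param model A \code{bpmm_model}.
#' @param settings An \code{mcmc_settings} object.
#' @return Object of class \code{bpmm_fit} with one element per chain, each
#'   holding the saved fixed-effect draws and the sampled covariance matrices
#'   per term (and per partition level).
#' @export
gibbs_run <- function(model, settings = mcmc_settings()) {
  stopifnot(inherits(model, "bpmm_model"), inherits(settings, "mcmc_settings"))
  cpp_terms <- lapply(unname(model$terms), function(bt)
    list(offset = bt$offset, q = bt$q, d = bt$d, iid = bt$iid, Ainv = bt$Ainv,
         S0 = bt$S0, nu0 = bt$nu0, fixed = bt$fixed, Sigma = bt$Sigma))
  ri <- model$resid_info
  marg <- !is.null(ri)
  resid_labels <- if (marg) {
    if (length(ri$levels) == 1 && ri$levels[1] == "") "resid" else
      paste("resid", ri$levels, sep = ".")
  } else character(0)
  term_names <- c(names(model$terms), resid_labels)

  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch - 1L)
    raw <- gibbs_core(model$data$y, model$w_ptr, model$w_idx, model$w_val,
                      model$p_theta, model$p_fixed, model$prior$v_beta,
                      cpp_terms,
                      marg,
                      if (marg) ri$level_index else integer(0),
                      if (marg) ri$n_levels else 0L,
                      if (marg) ri$S0 else numeric(0),
                      if (marg) ri$nu0 else 0,
                      if (marg) ri$fixed else FALSE,
                      if (marg) ri$sigma0 else numeric(0),
                      model$dvar,
                      settings$n_iterations, settings$burn_in, settings$thin)
    beta <- raw$beta[, seq_len(model$p_fixed), drop = FALSE]
    if (model$p_fixed > 0) colnames(beta) <- model$labels
    sigma <- raw$sigma
    names(sigma) <- names(model$terms)
    for (k in seq_along(sigma))
      dimnames(sigma[[k]]) <- list(model$traits, model$traits, NULL)
    if (marg) {
      for (l in seq_along(resid_labels)) {
        arr <- array(raw$rsigma[, l], dim = c(1, 1, nrow(raw$rsigma)))
        dimnames(arr) <- list(model$traits, model$traits, NULL)
        sigma[[resid_labels[l]]] <- arr
      }
    }
    chains[[ch]] <- list(beta = beta, sigma = sigma)
  }
  structure(list(chains = chains, labels = model$labels,
                 term_names = term_names, traits = model$traits,
                 settings = settings, model = model),
            class = "bpmm_fit")
}

#' @export
print.bpmm_fit <- function(x, ...) {
  cat("bpmm_fit:", length(x$chains), "chain(s) x", x$settings$n_save,
      "saved samples\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  fixed effects:", if (length(x$labels)) paste(x$labels, collapse = ", ")
      else "(none)", "\n")
  cat("  covariance terms:", paste(x$term_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract fixed-effect draws
#'
#' @param fit A \code{bpmm_fit}.
#' @param label Coefficient label (see \code{fit$labels}).
#' @param pooled Pool chains into one vector? Otherwise a matrix with one
#'   column per chain.
#' @return Numeric vector (pooled) or matrix of posterior draws.
#' @export
beta_samples <- function(fit, label, pooled = TRUE) {
  stopifnot(inherits(fit, "bpmm_fit"))
  if (!(label %in% fit$labels)) stop("unknown coefficient: ", label)
  m <- vapply(fit$chains, function(ch) ch$beta[, label],
              numeric(nrow(fit$chains[[1]]$beta)))
  if (pooled) as.numeric(m) else m
}

#' Extract covariance-matrix draws of one term
#'
#' @param fit A \code{bpmm_fit}.
#' @param term Term label, e.g. \code{"phylo"} or \code{"resid.vertical"}.
#' @param i,j Matrix entry to extract as a stream (defaults: full array).
#' @param pooled Pool chains along the iteration dimension?
#' @return If \code{i},\code{j} given: numeric vector (or matrix, one column
#'   per chain); otherwise a d x d x n array (pooled) or list of arrays.
#' @export
sigma_samples <- function(fit, term, i = NULL, j = NULL, pooled = TRUE) {
  stopifnot(inherits(fit, "bpmm_fit"))
  if (!(term %in% fit$term_names)) stop("unknown term: ", term)
  arrs <- lapply(fit$chains, function(ch) ch$sigma[[term]])
  if (!is.null(i)) {
    if (is.null(j)) j <- i
    m <- vapply(arrs, function(a) a[i, j, ], numeric(dim(arrs[[1]])[3]))
    return(if (pooled) as.numeric(m) else m)
  }
  if (!pooled) return(arrs)
  out <- array(unlist(arrs), dim = c(dim(arrs[[1]])[1:2],
                                     sum(vapply(arrs, function(a) dim(a)[3], 1L))))
  dimnames(out) <- list(fit$traits, fit$traits, NULL)
  out
}

#' Tidy posterior samples
#'
#' @param fit A \code{bpmm_fit}.
#' @return data.frame with columns chain, iteration, parameter, value
#'   (fixed effects and all covariance-matrix entries).
#' @export
posterior_df <- function(fit) {
  stopifnot(inherits(fit, "bpmm_fit"))
  rows <- list()
  for (ch in seq_along(fit$chains)) {
    b <- fit$chains[[ch]]$beta
    n <- nrow(b)
    for (lab in colnames(b))
      rows[[length(rows) + 1]] <- data.frame(chain = ch, iteration = seq_len(n),
                                             parameter = lab, value = b[, lab])
    for (tm in fit$term_names) {
      a <- fit$chains[[ch]]$sigma[[tm]]
      d <- dim(a)[1]
      for (i in seq_len(d)) for (j in i:d) {
        lab <- if (d == 1) tm else
          paste0(tm, "[", fit$traits[i], ",", fit$traits[j], "]")
        rows[[length(rows) + 1]] <- data.frame(chain = ch,
                                               iteration = seq_len(dim(a)[3]),
                                               parameter = lab, value = a[i, j, ])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
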