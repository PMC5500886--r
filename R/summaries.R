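#' Posterior mode of a sample stream
#'
#' The argmax of a Gaussian kernel density estimate (Silverman's bandwidth,
#' 512-point grid spanning the sample range), the point estimate conventionally
#' reported for variance components and effects from phylogenetic mixed models.
#'
#' @param samples Numeric vector of posterior draws.
#' @return The estimated mode (for constant input, that constant).
#' @export
posterior_mode <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty sample stream")
  rng <- range(samples)
  if (rng[2] - rng[1] <= 1e-10 * max(1, abs(rng[1])))  # constant up to fp noise
    return(median(samples))
  d <- density(samples, bw = "nrd0", n = 512,
               from = min(samples), to = max(samples))
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing \code{ceiling(mass * n)} of the
#' sorted samples (sliding-window minimization; ties broken toward the smallest
#' lower bound).
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass of the interval, in (0, 1).
#' @return Named numeric vector \code{c(lower, upper)}.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  xs <- sort(as.numeric(samples))
  n <- length(xs)
  if (n == 0) stop("empty sample stream")
  m <- min(n, ceiling(mass * n))
  widths <- xs[m:n] - xs[1:(n - m + 1)]
  i <- which.min(widths)  # first minimum = smallest lower bound
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Two-sided MCMC sign probability (pMCMC)
#'
#' Twice the smaller of the fractions of samples above and below zero,
#' floored at 2/n to correct for the finite number of MCMC samples and capped
#' at 1. Samples exactly zero count in neither sign.
#'
#' @param samples Numeric vector of posterior draws.
#' @return A value in (0, 1].
#' @export
pmcmc <- function(samples) {
  n <- length(samples)
  if (n == 0) stop("empty sample stream")
  np <- sum(samples > 0)
  nn <- sum(samples < 0)
  if (np == 0 && nn == 0) return(1)  # all-zero stream: no sign evidence at all
  min(1, 2 * max(1, min(np, nn)) / n)
}

#' Posterior summary: mode, 95\% HPD interval and pMCMC
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Credible mass of the interval.
#' @param interval \code{"hpd"} (default, shortest interval) or
#'   \code{"quantile"} (equal-tailed).
#' @return Object of class \code{summary_stats}: list with
#'   \code{posterior_mode}, \code{ci_lower}, \code{ci_upper}, \code{pmcmc},
#'   \code{n_samples}; the raw stream is kept in attribute \code{"samples"}.
#' @export
summary_stats <- function(samples, mass = 0.95, interval = c("hpd", "quantile")) {
  interval <- match.arg(interval)
  samples <- as.numeric(samples)
  ci <- if (interval == "hpd") hpd_interval(samples, mass) else
    quantile(samples, c((1 - mass) / 2, 1 - (1 - mass) / 2), names = FALSE)
  out <- list(posterior_mode = posterior_mode(samples),
              ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
              pmcmc = pmcmc(samples), n_samples = length(samples))
  attr(out, "samples") <- samples
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("posterior mode %.4g, 95%% CI [%.4g, %.4g], pMCMC %.4g (n = %d)\n",
              x$posterior_mode, x$ci_lower, x$ci_upper, x$pmcmc, x$n_samples))
  invisible(x)
}

#' Between-level difference of a fixed effect
#'
#' Builds the posterior of the difference between two factor levels by
#' per-iteration subtraction of their iteration-aligned coefficient streams,
#' then summarizes that difference stream.
#'
#' @param samples_level_a,samples_level_b Iteration-aligned draws of the two
#'   level coefficients.
#' @return \code{summary_stats} of the per-iteration difference a - b.
#' @export
fixed_effect_difference <- function(samples_level_a, samples_level_b) {
  if (length(samples_level_a) != length(samples_level_b))
    stop("sample streams must be iteration-aligned (equal length)")
  summary_stats(samples_level_a - samples_level_b)
}

#' Phylogenetic heritability
#'
#' Per-iteration percentage of trait variance attributable to the phylogenetic
#' random effect, \eqn{100 V_p / (V_p + V_r)}, summarized over the posterior.
#'
#' @param var_phylo,var_resid Iteration-aligned non-negative variance draws.
#' @return \code{summary_stats} of the heritability stream (percent, 0-100).
#' @export
phylo_heritability <- function(var_phylo, var_resid) {
  if (length(var_phylo) != length(var_resid))
    stop("variance streams must be iteration-aligned (equal length)")
  tot <- var_phylo + var_resid
  if (any(tot == 0)) stop("total variance is zero at iteration ",
                          which(tot == 0)[1])
  summary_stats(100 * var_phylo / tot)
}

#' Correlation stream from sampled 2x2 covariance matrices
#'
#' Per-iteration \eqn{r = C_{12} / \sqrt{C_{11} C_{22}}}.
#'
#' @param cov_matrices A 2 x 2 x n array, or a list of 2x2 matrices.
#' @return Numeric vector of per-iteration correlations, in [-1, 1].
#' @export
correlation_from_cov <- function(cov_matrices) {
  if (is.list(cov_matrices))
    cov_matrices <- array(unlist(cov_matrices), dim = c(2, 2, length(cov_matrices)))
  stopifnot(length(dim(cov_matrices)) == 3, all(dim(cov_matrices)[1:2] == 2))
  v1 <- cov_matrices[1, 1, ]
  v2 <- cov_matrices[2, 2, ]
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("zero or negative diagonal at iteration ",
         which(v1 <= 0 | v2 <= 0)[1])
  cov_matrices[1, 2, ] / sqrt(v1 * v2)
}

#' Difference between two correlation streams
#'
#' Summarizes the per-iteration difference r_a - r_b and reports the fraction
#' of iterations with r_a strictly greater than r_b (ties contribute 0).
#'
#' @param r_a,r_b Iteration-aligned correlation streams in [-1, 1].
#' @return List with \code{diff} (a \code{summary_stats} of r_a - r_b) and
#'   \code{proportion_a_greater}.
#' @export
correlation_difference_test <- function(r_a, r_b) {
  if (length(r_a) != length(r_b))
    stop("correlation streams must be iteration-aligned (equal length)")
  list(diff = summary_stats(r_a - r_b),
       proportion_a_greater = mean(r_a > r_b))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\sqrt{((n-1)/n \cdot W + B/n)/W}} with W the mean within-chain variance
#' and B = n times the between-chain variance of the chain means. Values near
#' 1 indicate the chains are sampling the same distribution.
#'
#' @param chains A list of >= 2 equal-length numeric chains, or a matrix with
#'   one chain per column.
#' @return The PSRF (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("gelman_rubin requires at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  W <- mean(vapply(chains, var, 1.0))
  B <- n * var(vapply(chains, mean, 1.0))
  if (W == 0) return(1.0)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first \code{frac_a} of a chain with the mean of
#' the last \code{frac_b}, standardized by batch-means standard errors
#' (20 batches per segment). |z| < 2 is the conventional stationarity check.
#'
#' @param chain Numeric chain of length >= 200.
#' @param frac_a,frac_b Leading and trailing fractions to compare.
#' @param n_batches Number of batches for the variance estimate.
#' @return The z-score (0 for a constant chain).
#' @export
geweke <- function(chain, frac_a = 0.1, frac_b = 0.5, n_batches = 20) {
  n <- length(chain)
  if (n < 200) stop("chain too short for Geweke diagnostic (need >= 200)")
  seg_a <- chain[seq_len(floor(frac_a * n))]
  seg_b <- chain[(n - floor(frac_b * n) + 1):n]
  batch_se <- function(x) {
    k <- min(n_batches, length(x))
    means <- vapply(split(x, cut(seq_along(x), k, labels = FALSE)), mean, 1.0)
    sqrt(var(means) / k)
  }
  se_a <- batch_se(seg_a)
  se_b <- batch_se(seg_b)
  denom <- sqrt(se_a^2 + se_b^2)
  num <- mean(seg_a) - mean(seg_b)
  if (denom == 0) return(0)
  num / denom
}
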