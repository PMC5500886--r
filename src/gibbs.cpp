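// Gibbs sampler core for Gaussian (phylogenetic) mixed models.
//
// Model, in long format over M rows (one row = one trait value of one
// observation unit):
//   y_r = w_r' theta + e_{unit(r)} + eps_r,  eps_r ~ N(0, mev_r) known
//   theta = (beta, effects of term 1, ..., effects of term K)
//   beta ~ N(0, v_beta I)
//   term k: q_k levels x d_k traits, vec(E_k) ~ N(0, Sigma_k (x) A_k)
//   residual effects e: one per unit, covariance R (per partition level)
//   Sigma, R ~ IW(nu, S0)   [S0 = nu * V in the (V, nu) prior convention]
//
// Location effects are drawn as ONE joint Gaussian block from the
// mixed-model equations; covariance matrices then come from their conjugate
// inverse-Wishart conditionals. Two residual treatments:
//  * marginal path (single trait, one row per unit): e is integrated into
//    the observation variance (mev_r + sigma_l), the location block excludes
//    it, and e is drawn afterwards from its exact conditional only to feed
//    the scalar residual-variance update. Much smaller Cholesky.
//  * explicit path (multi-trait / shared units): e is part of theta and the
//    residual covariance is one more inverse-Wishart term.
// The two paths target the same posterior.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sigma ~ InverseWishart(df, S) via Bartlett on the Wishart(df, S^-1) draw.
// Uses R's RNG so chains reproduce from set.seed().
static arma::mat riwish(double df, const arma::mat& S) {
  const int d = S.n_rows;
  if (d == 1) {
    double s = std::max(S(0, 0), 1e-12);
    return arma::mat(1, 1, arma::fill::value(s / R::rchisq(df)));
  }
  arma::mat L = arma::chol(arma::inv_sympd(arma::symmatu(S)), "lower");
  arma::mat T(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    T(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) T(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat LT = L * T;
  return arma::inv_sympd(arma::symmatu(LT * LT.t()));
}

// Symmetrize and floor eigenvalues (numerical guard on conditional scales).
static arma::mat floor_sympd(const arma::mat& M, double eps) {
  if (M.n_rows == 1) {
    arma::mat out = M;
    out(0, 0) = std::max(out(0, 0), eps);
    return out;
  }
  arma::mat S = arma::symmatu((M + M.t()) / 2.0);
  arma::vec ev;
  arma::mat V;
  if (!arma::eig_sym(ev, V, S)) Rcpp::stop("eigendecomposition failed");
  ev = arma::clamp(ev, eps, arma::datum::inf);
  return V * arma::diagmat(ev) * V.t();
}

struct Term {
  int offset, q, d;
  bool iid, fixed;
  arma::mat Ainv, S0, Sigma;
  double nu0;
};

// [[Rcpp::export]]
List gibbs_core(const arma::vec& y,
                const arma::uvec& w_ptr,   // CSR row pointers (0-based, M+1)
                const arma::uvec& w_idx,   // CSR column indices (0-based)
                const arma::vec& w_val,
                int p_theta, int p_fixed, double v_beta, List terms,
                bool resid_marg,
                const arma::uvec& resid_level,  // per row, 0-based (marg path)
                int n_rlev, const arma::vec& resid_S0, double resid_nu0,
                bool resid_fixed, const arma::vec& resid_sigma0,
                const arma::vec& mev,
                int n_iter, int burn_in, int thin) {
  const int M = y.n_elem;
  const int K = terms.size();

  std::vector<Term> tm(K);
  for (int k = 0; k < K; ++k) {
    List t = terms[k];
    tm[k].offset = as<int>(t["offset"]);
    tm[k].q = as<int>(t["q"]);
    tm[k].d = as<int>(t["d"]);
    tm[k].iid = as<bool>(t["iid"]);
    tm[k].fixed = as<bool>(t["fixed"]);
    tm[k].Ainv = as<arma::mat>(t["Ainv"]);
    tm[k].S0 = as<arma::mat>(t["S0"]);
    tm[k].nu0 = as<double>(t["nu0"]);
    tm[k].Sigma = as<arma::mat>(t["Sigma"]);
  }
  arma::vec rsigma = resid_sigma0;          // per-level residual variance
  arma::uvec q_rlev(std::max(n_rlev, 1), arma::fill::zeros);
  if (resid_marg)
    for (int r = 0; r < M; ++r) q_rlev(resid_level(r)) += 1;

  const int n_save = (n_iter - burn_in) / thin;
  arma::mat beta_save(n_save, std::max(p_fixed, 1), arma::fill::zeros);
  std::vector<arma::cube> sigma_save(K);
  for (int k = 0; k < K; ++k)
    sigma_save[k] = arma::cube(tm[k].d, tm[k].d, n_save, arma::fill::zeros);
  arma::mat rsig_save(n_save, std::max(n_rlev, 1), arma::fill::zeros);

  arma::mat P(p_theta, p_theta);
  arma::vec b(p_theta), theta(p_theta, arma::fill::zeros), z(p_theta),
    dinv(M), resid(M);
  int isave = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // observation precision (marginal path folds the residual variance in)
    for (int r = 0; r < M; ++r) {
      double v = mev(r);
      if (resid_marg) v += rsigma(resid_level(r));
      dinv(r) = 1.0 / v;
    }

    if (p_theta > 0) {
      // --- location block: theta | Sigma, y ---
      P.zeros();
      b.zeros();
      for (int r = 0; r < M; ++r) {
        const double dr = dinv(r);
        for (arma::uword a = w_ptr(r); a < w_ptr(r + 1); ++a) {
          const int ca = w_idx(a);
          const double va = w_val(a) * dr;
          b(ca) += va * y(r);
          for (arma::uword bb = w_ptr(r); bb < w_ptr(r + 1); ++bb)
            P(ca, w_idx(bb)) += va * w_val(bb);
        }
      }
      for (int i = 0; i < p_fixed; ++i) P(i, i) += 1.0 / v_beta;
      for (int k = 0; k < K; ++k) {
        const Term& t = tm[k];
        arma::mat Sinv = arma::inv_sympd(arma::symmatu(t.Sigma));
        if (t.iid) {
          for (int ti = 0; ti < t.d; ++ti)
            for (int tj = 0; tj < t.d; ++tj) {
              const double s = Sinv(ti, tj);
              for (int g = 0; g < t.q; ++g)
                P(t.offset + ti * t.q + g, t.offset + tj * t.q + g) += s;
            }
        } else {
          for (int ti = 0; ti < t.d; ++ti)
            for (int tj = 0; tj < t.d; ++tj)
              P.submat(t.offset + ti * t.q, t.offset + tj * t.q,
                       t.offset + (ti + 1) * t.q - 1,
                       t.offset + (tj + 1) * t.q - 1) += Sinv(ti, tj) * t.Ainv;
        }
      }
      arma::mat U;
      if (!arma::chol(U, arma::symmatu(P))) {
        P.diag() += 1e-8 * arma::max(P.diag());
        if (!arma::chol(U, arma::symmatu(P)))
          stop("non-positive-definite conditional at iteration %d", it);
      }
      arma::vec mu = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), b));
      for (int i = 0; i < p_theta; ++i) z(i) = R::rnorm(0.0, 1.0);
      theta = mu + arma::solve(arma::trimatu(U), z);
    }

    // --- covariance blocks: Sigma_k | E_k ---
    for (int k = 0; k < K; ++k) {
      Term& t = tm[k];
      if (t.fixed) continue;
      arma::mat E(theta.memptr() + t.offset, t.q, t.d);
      arma::mat cross = t.iid ? arma::mat(E.t() * E)
                              : arma::mat(E.t() * t.Ainv * E);
      arma::mat scale = floor_sympd(t.S0 + cross, 1e-10);
      t.Sigma = riwish(t.nu0 + t.q, scale);
    }

    // --- marginalized residual: draw e | theta, y then sigma_l | e ---
    if (resid_marg && !resid_fixed) {
      for (int r = 0; r < M; ++r) {
        double fit = 0.0;
        for (arma::uword a = w_ptr(r); a < w_ptr(r + 1); ++a)
          fit += w_val(a) * theta(w_idx(a));
        resid(r) = y(r) - fit;
      }
      arma::vec ss(n_rlev, arma::fill::zeros);
      for (int r = 0; r < M; ++r) {
        const int l = resid_level(r);
        const double s = rsigma(l), m = mev(r);
        const double cvar = s * m / (s + m);
        const double cmean = resid(r) * s / (s + m);
        const double e = cmean + R::rnorm(0.0, 1.0) * std::sqrt(cvar);
        ss(l) += e * e;
      }
      for (int l = 0; l < n_rlev; ++l)
        rsigma(l) = std::max(resid_S0(l) + ss(l), 1e-12) /
          R::rchisq(resid_nu0 + q_rlev(l));
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && isave < n_save) {
      if (p_fixed > 0) beta_save.row(isave) = theta.head(p_fixed).t();
      for (int k = 0; k < K; ++k) sigma_save[k].slice(isave) = tm[k].Sigma;
      if (resid_marg) rsig_save.row(isave) = rsigma.t();
      ++isave;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List sig_out(K);
  for (int k = 0; k < K; ++k) sig_out[k] = sigma_save[k];
  return List::create(_["beta"] = beta_save, _["sigma"] = sig_out,
                      _["rsigma"] = rsig_save, _["n_saved"] = isave);
}
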