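// Compiled core for the generalised Wishart process: kernel Gram matrices,
// the multivariate-normal likelihood of the constructed covariance process,
// and the Gibbs cycle (elliptical slice sampling for the latent GPs,
// random-walk Metropolis for kernel hyperparameters and the scale Cholesky).
// All randomness comes from R's RNG so set.seed() controls every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// kernel kinds: 1 rbf(ell) | 2 periodic(p, ell_p) | 3 locally_periodic(p, ell_p, ell)
//               4 matern12(ell_m) | 5 sum_rbf_matern12(ell, ell_m)
// The Matern-1/2 term uses the squared-lengthscale form exp(-r / (2 l^2)).
static inline double kern1(int kind, const arma::vec& par, double r) {
  switch (kind) {
  case 1:
    return std::exp(-(r * r) / (2.0 * par[0] * par[0]));
  case 2: {
    double s = std::sin(M_PI * std::abs(r) / par[0]);
    return std::exp(-2.0 * s * s / (par[1] * par[1]));
  }
  case 3: {
    double s = std::sin(M_PI * std::abs(r) / par[0]);
    return std::exp(-2.0 * s * s / (par[1] * par[1])) *
           std::exp(-(r * r) / (2.0 * par[2] * par[2]));
  }
  case 4:
    return std::exp(-std::abs(r) / (2.0 * par[0] * par[0]));
  case 5:
    return std::exp(-(r * r) / (2.0 * par[0] * par[0])) +
           std::exp(-std::abs(r) / (2.0 * par[1] * par[1]));
  default:
    stop("unknown kernel kind code");
  }
  return NA_REAL; // unreachable
}

// [[Rcpp::export]]
arma::mat gwp_gram_cpp(int kind, const arma::vec& par, const arma::vec& x,
                       double jitter) {
  const arma::uword n = x.n_elem;
  arma::mat K(n, n);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = i; j < n; ++j) {
      double v = kern1(kind, par, x[i] - x[j]);
      K(i, j) = v;
      K(j, i) = v;
    }
    K(i, i) += jitter;
  }
  return K;
}

// [[Rcpp::export]]
arma::cube gwp_sigma_cpp(const arma::cube& F, const arma::mat& L) {
  // F: d x v x n, slice i holds the latent values at input i.
  const arma::uword d = F.n_rows, n = F.n_slices;
  arma::cube Sig(d, d, n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat A = L * F.slice(i);
    Sig.slice(i) = A * A.t();
  }
  return Sig;
}

static inline double mvn_ll_slice(const arma::vec& y, const arma::mat& S) {
  arma::mat C;
  if (!arma::chol(C, S, "lower")) return -std::numeric_limits<double>::infinity();
  arma::vec z = arma::solve(arma::trimatl(C), y);
  double logdet = 2.0 * arma::accu(arma::log(C.diag()));
  return -0.5 * (y.n_elem * LOG2PI + logdet + arma::dot(z, z));
}

// per-observation log-density of rows of Yc under N(0, L F_i F_i' L' + jitter I)
// [[Rcpp::export]]
arma::vec gwp_loglik_obs_cpp(const arma::mat& Yc, const arma::cube& F,
                             const arma::mat& L, double jitter) {
  const arma::uword n = Yc.n_rows, d = Yc.n_cols;
  arma::vec out(n);
  arma::mat J = jitter * arma::eye(d, d);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat A = L * F.slice(i);
    out[i] = mvn_ll_slice(Yc.row(i).t(), A * A.t() + J);
  }
  return out;
}

// Hand-rolled hot path: per input, S = L F_i F_i' L' + jitter I is built
// with plain loops and factorised with a small in-place Cholesky. Avoids
// per-slice Armadillo temporaries, which dominate runtime for small d.
static double gwp_loglik(const arma::mat& Yc, const arma::cube& F,
                         const arma::mat& L, double jitter) {
  const arma::uword n = Yc.n_rows, d = Yc.n_cols, v = F.n_cols;
  const double* fp = F.memptr();
  const double* lp = L.memptr(); // column-major d x d
  std::vector<double> A(d * v), S(d * d), z(d);
  double tot = 0.0;
  const double neg_inf = -std::numeric_limits<double>::infinity();
  for (arma::uword i = 0; i < n; ++i) {
    const double* Fi = fp + i * d * v; // column-major d x v slice
    // A = L * F_i, exploiting the lower triangle of L
    for (arma::uword c = 0; c < v; ++c)
      for (arma::uword r = 0; r < d; ++r) {
        double s = 0.0;
        for (arma::uword k = 0; k <= r; ++k)
          s += lp[r + k * d] * Fi[k + c * d];
        A[r + c * d] = s;
      }
    // S = A A' + jitter I (lower triangle only)
    for (arma::uword r = 0; r < d; ++r)
      for (arma::uword c = 0; c <= r; ++c) {
        double s = 0.0;
        for (arma::uword k = 0; k < v; ++k)
          s += A[r + k * d] * A[c + k * d];
        S[r + c * d] = s + (r == c ? jitter : 0.0);
      }
    // in-place lower Cholesky of S
    double logdet = 0.0;
    bool ok = true;
    for (arma::uword c = 0; c < d && ok; ++c) {
      double diag = S[c + c * d];
      for (arma::uword k = 0; k < c; ++k) diag -= S[c + k * d] * S[c + k * d];
      if (diag <= 0.0) { ok = false; break; }
      diag = std::sqrt(diag);
      S[c + c * d] = diag;
      logdet += 2.0 * std::log(diag);
      for (arma::uword r = c + 1; r < d; ++r) {
        double s = S[r + c * d];
        for (arma::uword k = 0; k < c; ++k) s -= S[r + k * d] * S[c + k * d];
        S[r + c * d] = s / diag;
      }
    }
    if (!ok) return neg_inf;
    // z = S^{-1/2} y, forward substitution
    double quad = 0.0;
    for (arma::uword r = 0; r < d; ++r) {
      double s = Yc(i, r);
      for (arma::uword k = 0; k < r; ++k) s -= S[r + k * d] * z[k];
      z[r] = s / S[r + r * d];
      quad += z[r] * z[r];
    }
    tot += -0.5 * (d * LOG2PI + logdet + quad);
  }
  return tot;
}

// [[Rcpp::export]]
double gwp_loglik_cpp(const arma::mat& Yc, const arma::cube& F,
                      const arma::mat& L, double jitter) {
  return gwp_loglik(Yc, F, L, jitter);
}

// log p(F | K) for all d*v latent rows, K given through its lower Cholesky
static double f_prior_ll(const arma::cube& F, const arma::mat& Lk) {
  const arma::uword d = F.n_rows, v = F.n_cols, n = F.n_slices;
  double logdet = 2.0 * arma::accu(arma::log(Lk.diag()));
  double tot = 0.0;
  const double* fp = F.memptr();
  const double* lk = Lk.memptr();
  std::vector<double> f(n), z(n);
  for (arma::uword j = 0; j < d; ++j) {
    for (arma::uword l = 0; l < v; ++l) {
      for (arma::uword i = 0; i < n; ++i) f[i] = fp[j + l * d + i * d * v];
      // forward substitution, quadratic form accumulated on the fly
      double quad = 0.0;
      for (arma::uword r = 0; r < n; ++r) {
        double s = f[r];
        for (arma::uword k = 0; k < r; ++k) s -= lk[r + k * n] * z[k];
        z[r] = s / lk[r + r * n];
        quad += z[r] * z[r];
      }
      tot += -0.5 * (n * LOG2PI + logdet + quad);
    }
  }
  return tot;
}

// [[Rcpp::export]]
double gwp_fprior_cpp(const arma::cube& F, const arma::mat& Lk) {
  return f_prior_ll(F, Lk);
}

static inline double runif_ab(double a, double b) {
  return a + (b - a) * unif_rand();
}

// One elliptical slice move on latent row (j,l); tempered target
// p(Y|F,L)^beta * p(F|theta). Updates F and cur_ll in place.
static void ess_move(arma::cube& F, arma::uword j, arma::uword l,
                     const arma::mat& Yc, const arma::mat& L,
                     const arma::mat& Lk, double beta, double jitter,
                     double& cur_ll) {
  const arma::uword n = F.n_slices;
  arma::vec f(n), z(n);
  for (arma::uword i = 0; i < n; ++i) {
    f[i] = F(j, l, i);
    z[i] = norm_rand();
  }
  arma::vec nu = Lk * z;
  // slice level on the tempered likelihood; at beta = 0 the first proposal
  // is accepted with probability 1 (log u < 0 a.s.), a pure prior move
  double logy = beta * cur_ll + std::log(unif_rand());
  double ang = runif_ab(0.0, 2.0 * M_PI);
  double lo = ang - 2.0 * M_PI, hi = ang;
  for (int it = 0; it < 100; ++it) {
    for (arma::uword i = 0; i < n; ++i)
      F(j, l, i) = f[i] * std::cos(ang) + nu[i] * std::sin(ang);
    if (beta == 0.0) {
      cur_ll = gwp_loglik(Yc, F, L, jitter);
      return;
    }
    double ll = gwp_loglik(Yc, F, L, jitter);
    if (beta * ll > logy) {
      cur_ll = ll;
      return;
    }
    if (ang < 0.0) lo = ang; else hi = ang;
    ang = runif_ab(lo, hi);
  }
  // bracket exhausted (should not happen for continuous targets): restore
  for (arma::uword i = 0; i < n; ++i) F(j, l, i) = f[i];
}

// Run n_cycles Gibbs cycles (F -> theta -> L). Returns the final state plus
// draws collected every `collect_every` cycles (0 = keep none).
// [[Rcpp::export]]
List gwp_cycles_cpp(const arma::mat& Yc, const arma::vec& x,
                    const arma::cube& F_in, const arma::vec& logtheta_in,
                    int kind, const arma::vec& prior_mu,
                    const arma::vec& prior_sd, const arma::mat& L_in,
                    double beta, double rw_step, double jitter, int n_cycles,
                    bool update_theta, int collect_every,
                    bool update_latent = true, bool update_scale = true) {
  // explicit copies: the const& inputs may alias R-side memory
  arma::cube F = F_in;
  arma::vec logtheta = logtheta_in;
  arma::mat L = L_in;
  const arma::uword d = F.n_rows;
  arma::mat Lk;
  {
    // escalate the jitter by decades (to 1e-2) before giving up, mirroring
    // the R-level policy; near-commensurate periodic kernels are the
    // typical trigger
    arma::mat K = gwp_gram_cpp(kind, arma::exp(logtheta), x, 0.0);
    double j = std::max(jitter, 1e-12);
    bool ok = false;
    while (!ok && j <= 1e-2 * 1.0000001) {
      ok = arma::chol(Lk, K + j * arma::eye(x.n_elem, x.n_elem), "lower");
      if (!ok) j *= 10.0;
    }
    if (!ok) stop("Gram Cholesky failed at current hyperparameters");
  }
  double cur_ll = gwp_loglik(Yc, F, L, jitter);
  int acc_theta = 0, n_theta = 0, acc_L = 0, n_L = 0;
  std::vector<arma::cube> draws_F;
  std::vector<arma::vec> draws_theta;
  std::vector<arma::mat> draws_L;
  std::vector<double> draws_ll;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // --- latent GP rows, elliptical slice ---
    if (update_latent)
      for (arma::uword j = 0; j < d; ++j)
        for (arma::uword l = 0; l < F.n_cols; ++l)
          ess_move(F, j, l, Yc, L, Lk, beta, jitter, cur_ll);

    // --- kernel hyperparameters: RWMH on log theta; the conditional is
    //     p(F|x,theta) p(theta) and never sees Y ---
    if (update_theta) {
      ++n_theta;
      arma::vec prop = logtheta;
      for (arma::uword k = 0; k < prop.n_elem; ++k) prop[k] += rw_step * norm_rand();
      arma::mat Kp = gwp_gram_cpp(kind, arma::exp(prop), x, 0.0);
      arma::mat Lkp;
      bool okp = false;
      {
        double j = std::max(jitter, 1e-12);
        while (!okp && j <= 1e-2 * 1.0000001) {
          okp = arma::chol(Lkp, Kp + j * arma::eye(x.n_elem, x.n_elem),
                           "lower");
          if (!okp) j *= 10.0;
        }
      }
      if (okp) {
        double cur_fp = f_prior_ll(F, Lk);
        double prop_fp = f_prior_ll(F, Lkp);
        double lr = prop_fp - cur_fp;
        for (arma::uword k = 0; k < prop.n_elem; ++k) {
          lr += -0.5 * std::pow((prop[k] - prior_mu[k]) / prior_sd[k], 2.0);
          lr -= -0.5 * std::pow((logtheta[k] - prior_mu[k]) / prior_sd[k], 2.0);
        }
        if (std::log(unif_rand()) < lr) {
          logtheta = prop;
          Lk = Lkp;
          ++acc_theta;
        }
      }
    }

    // --- scale Cholesky: joint RWMH on the d(d+1)/2 free entries,
    //     target p(Y|F,L)^beta * prod N(L_jo | 0, 1) ---
    if (update_scale) {
      ++n_L;
      arma::mat Lp = L;
      double dprior = 0.0;
      for (arma::uword jj = 0; jj < d; ++jj) {
        for (arma::uword oo = 0; oo <= jj; ++oo) {
          double nv = L(jj, oo) + rw_step * norm_rand();
          dprior += -0.5 * nv * nv + 0.5 * L(jj, oo) * L(jj, oo);
          Lp(jj, oo) = nv;
        }
      }
      double prop_ll = gwp_loglik(Yc, F, Lp, jitter);
      double lr = dprior + (beta > 0.0 ? beta * (prop_ll - cur_ll) : 0.0);
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        L = Lp;
        cur_ll = prop_ll;
        ++acc_L;
      }
    }

    if (collect_every > 0 && ((cyc + 1) % collect_every == 0)) {
      draws_F.push_back(F);
      draws_theta.push_back(logtheta);
      draws_L.push_back(L);
      draws_ll.push_back(cur_ll);
    }
  }

  List dF(draws_F.size()), dT(draws_theta.size()), dL(draws_L.size());
  for (size_t i = 0; i < draws_F.size(); ++i) {
    dF[i] = draws_F[i];
    dT[i] = draws_theta[i];
    dL[i] = draws_L[i];
  }
  return List::create(
      _["F"] = F, _["logtheta"] = logtheta, _["L"] = L, _["loglik"] = cur_ll,
      _["acc_theta"] = n_theta ? double(acc_theta) / n_theta : NA_REAL,
      _["acc_L"] = n_L ? double(acc_L) / n_L : NA_REAL,
      _["draws_F"] = dF, _["draws_theta"] = dT, _["draws_L"] = dL,
      _["draws_ll"] = wrap(draws_ll));
}

// Likelihood value and gradients for the variational baseline:
// sum_i log N(y_i | 0, L F_i F_i' L' + diag(lambda)), with gradients wrt
// F (cube), L (full matrix; caller masks the lower triangle) and lambda.
// [[Rcpp::export]]
List gwp_vi_likgrad_cpp(const arma::mat& Yc, const arma::cube& F,
                        const arma::mat& L, const arma::vec& lambda) {
  const arma::uword n = Yc.n_rows, d = Yc.n_cols;
  arma::cube gF(arma::size(F), arma::fill::zeros);
  arma::mat gL(d, d, arma::fill::zeros);
  arma::vec glam(d, arma::fill::zeros);
  double val = 0.0;
  arma::mat Lam = arma::diagmat(lambda);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat Fi = F.slice(i);
    arma::mat A = L * Fi;
    arma::mat S = A * A.t() + Lam;
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, S))
      return List::create(_["value"] = R_NegInf);
    arma::vec y = Yc.row(i).t();
    arma::vec alpha = Sinv * y;
    double ldet;
    double sign;
    arma::log_det(ldet, sign, S);
    val += -0.5 * (d * LOG2PI + ldet + arma::dot(y, alpha));
    arma::mat G = 0.5 * (alpha * alpha.t() - Sinv);
    gF.slice(i) = 2.0 * L.t() * G * A;
    gL += 2.0 * G * L * (Fi * Fi.t());
    glam += G.diag();
  }
  return List::create(_["value"] = val, _["gF"] = gF, _["gL"] = gL,
                      _["glambda"] = glam);
}
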