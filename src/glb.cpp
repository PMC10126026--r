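// Greatest lower bound to reliability via the minimum-trace SDP:
//
//   maximize   sum(theta)
//   subject to Sigma - diag(theta) psd,  0 <= theta_i <= sigma_ii
//
// The decision vector theta has only k (<= ~10 here) entries, so the
// problem is solved by a primal log-barrier interior-point method with
// exact damped Newton steps:
//
//   f_mu(theta) = sum(theta) + mu [ log det(Sigma - diag(theta))
//                                   + sum log theta_i
//                                   + sum log(sigma_ii - theta_i) ]
//
// f_mu is strictly concave; with M = (Sigma - diag(theta))^-1,
//   grad_i = 1 - mu M_ii + mu / theta_i - mu / (sigma_ii - theta_i)
//   -Hess_ij = mu M_ij^2 + delta_ij mu (theta_i^-2 + (sigma_ii-theta_i)^-2)
// The barrier parameter follows a geometric path; the suboptimality of the
// final iterate is bounded by 3 k mu_final, so mu_final = tol / (3 k)
// certifies the requested accuracy. The caller rescales Sigma to unit mean
// diagonal first, making tol scale-free (glb is invariant under c^2*Sigma).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct GlbFit {
  double value;
  int newton_steps;
  bool converged;
  double mu_final;
  vec theta;
};

static double barrier_val(const mat& S, const vec& dS, const vec& theta,
                          double mu, bool& ok) {
  mat T = S;
  T.diag() -= theta;
  mat ch;
  ok = chol(ch, symmatu(T));
  if (!ok) return -datum::inf;
  if (theta.min() <= 0.0 || (dS - theta).min() <= 0.0) { ok = false; return -datum::inf; }
  double logdet = 2.0 * accu(log(ch.diag()));
  return accu(theta) + mu * (logdet + accu(log(theta)) + accu(log(dS - theta)));
}

static GlbFit glb_barrier(const mat& S_in, double tol, int max_iter) {
  const uword k = S_in.n_rows;
  GlbFit fit;
  fit.newton_steps = 0;

  mat S = symmatu(S_in);
  vec dS = S.diag();
  const double total = accu(S);

  // degenerate: (numerically) diagonal matrix -> theta = diag, glb = 0
  mat off = S;
  off.diag().zeros();
  if (norm(off, "fro") < 1e-14 * std::max(1.0, norm(S, "fro"))) {
    fit.value = 1.0 - accu(dS) / total;
    fit.converged = true;
    fit.mu_final = 0.0;
    fit.theta = dS;
    return fit;
  }

  // strict interior needs Sigma pd: ridge exactly-singular input by a
  // negligible amount (value perturbation far below tol)
  double lmin = eig_sym(S).min();
  double smax = dS.max();
  if (lmin < 1e-12 * smax) {
    S.diag() += (1e-12 * smax - lmin);
    dS = S.diag();
    lmin = 1e-12 * smax;
  }

  vec theta = vec(k);
  theta.fill(std::min(0.5 * lmin, 0.25 * dS.min()));

  const double mu_final = tol / (3.0 * k);
  double mu = 1.0;
  bool ok;

  while (true) {
    // damped Newton on f_mu to tolerance proportional to mu
    for (int step = 0; step < 60; ++step) {
      if (fit.newton_steps >= max_iter) {
        fit.value = 1.0 - accu(clamp(theta, 0.0, datum::inf)) / total;
        fit.converged = false;
        fit.mu_final = mu;
        fit.theta = theta;
        return fit;
      }
      mat T = S;
      T.diag() -= theta;
      mat M = inv_sympd(symmatu(T));
      vec g = 1.0 - mu * M.diag() + mu / theta - mu / (dS - theta);
      mat H = mu * (M % M);
      H.diag() += mu * (1.0 / square(theta) + 1.0 / square(dS - theta));
      vec d = solve(H, g, solve_opts::likely_sympd);
      double decr = dot(g, d);
      if (decr < 0) d = g / norm(g);  // fallback, should not trigger
      if (std::sqrt(std::max(decr, 0.0)) < 1e-8 + 0.05 * mu) break;

      double f0 = barrier_val(S, dS, theta, mu, ok);
      double t = 1.0;
      vec cand;
      for (int ls = 0; ls < 60; ++ls) {
        cand = theta + t * d;
        double f1 = barrier_val(S, dS, cand, mu, ok);
        if (ok && f1 >= f0 + 0.25 * t * decr) break;
        t *= 0.5;
        if (ls == 59) cand = theta;  // stalled line search
      }
      theta = cand;
      ++fit.newton_steps;
    }
    if (mu <= mu_final) break;
    mu = std::max(mu * 0.15, mu_final);
  }

  fit.value = 1.0 - accu(theta) / total;
  fit.converged = true;
  fit.mu_final = mu;
  fit.theta = theta;
  return fit;
}

// [[Rcpp::export(name = ".glb_solve")]]
Rcpp::List glb_solve(const arma::mat& sigma, double tol = 1e-8,
                     int max_iter = 10000) {
  double scale = mean(sigma.diag());
  GlbFit fit = glb_barrier(sigma / scale, tol, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("value") = fit.value,
      Rcpp::Named("iterations") = fit.newton_steps,
      Rcpp::Named("converged") = fit.converged,
      Rcpp::Named("mu_final") = fit.mu_final);
}

// vectorized over a k x k x N array of covariance draws
// [[Rcpp::export(name = ".glb_solve_many")]]
Rcpp::NumericVector glb_solve_many(const arma::cube& sigmas,
                                   double tol = 1e-8, int max_iter = 10000) {
  const uword N = sigmas.n_slices;
  Rcpp::NumericVector out(N);
  for (uword s = 0; s < N; ++s) {
    mat Si = sigmas.slice(s);
    double scale = mean(Si.diag());
    if (scale > 0) Si /= scale;
    GlbFit fit = glb_barrier(Si, tol, max_iter);
    out[s] = std::min(std::max(fit.value, 0.0), 1.0);
  }
  return out;
}
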