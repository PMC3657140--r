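// Forward model for the 4-region bilinear DCM: neural states advance by the
// exact matrix-exponential update of the (piecewise-constant-input) bilinear
// system; hemodynamic (balloon-windkessel) states advance by RK4 on the same
// microtime grid. Inputs are boxcars, so the exponential is recomputed only
// when the input row changes (a handful of times per scan).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void hemo_deriv(const vec &x, const vec &s, const vec &f,
                              const vec &v, const vec &q, const mat &hemo,
                              vec &ds, vec &df, vec &dv, vec &dq) {
  // hemo columns: kappa, gamma, tau, alpha, e0
  const int R = x.n_elem;
  for (int r = 0; r < R; ++r) {
    const double kappa = hemo(r, 0), gamma = hemo(r, 1), tau = hemo(r, 2),
                 alpha = hemo(r, 3), e0 = hemo(r, 4);
    const double fv = std::pow(v(r), 1.0 / alpha);
    const double ef = 1.0 - std::pow(1.0 - e0, 1.0 / f(r));
    ds(r) = x(r) - kappa * s(r) - gamma * (f(r) - 1.0);
    df(r) = s(r);
    dv(r) = (f(r) - fv) / tau;
    dq(r) = (f(r) * ef / e0 - fv * q(r) / v(r)) / tau;
  }
}

// One RK4 step for the hemodynamic states, with the neural drive supplied at
// the start, middle and end of the bin.
static inline void hemo_rk4(const vec &xa, const vec &xm, const vec &xb,
                            vec &s, vec &f, vec &v, vec &q, const mat &hemo,
                            double dt) {
  const int R = s.n_elem;
  vec k1s(R), k1f(R), k1v(R), k1q(R), k2s(R), k2f(R), k2v(R), k2q(R),
      k3s(R), k3f(R), k3v(R), k3q(R), k4s(R), k4f(R), k4v(R), k4q(R);
  hemo_deriv(xa, s, f, v, q, hemo, k1s, k1f, k1v, k1q);
  vec s2 = s + 0.5 * dt * k1s, f2 = f + 0.5 * dt * k1f,
      v2 = v + 0.5 * dt * k1v, q2 = q + 0.5 * dt * k1q;
  hemo_deriv(xm, s2, f2, v2, q2, hemo, k2s, k2f, k2v, k2q);
  vec s3 = s + 0.5 * dt * k2s, f3 = f + 0.5 * dt * k2f,
      v3 = v + 0.5 * dt * k2v, q3 = q + 0.5 * dt * k2q;
  hemo_deriv(xm, s3, f3, v3, q3, hemo, k3s, k3f, k3v, k3q);
  vec s4 = s + dt * k3s, f4 = f + dt * k3f, v4 = v + dt * k3v,
      q4 = q + dt * k3q;
  hemo_deriv(xb, s4, f4, v4, q4, hemo, k4s, k4f, k4v, k4q);
  s += dt / 6.0 * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);
  f += dt / 6.0 * (k1f + 2.0 * k2f + 2.0 * k3f + k4f);
  v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
  q += dt / 6.0 * (k1q + 2.0 * k2q + 2.0 * k3q + k4q);
}

// [[Rcpp::export]]
arma::mat dcm_integrate_cpp(const arma::mat &A, const arma::cube &B,
                            const arma::mat &C, const arma::mat &U,
                            const arma::mat &hemo, double V0, double dt,
                            const arma::uvec &sample_bins) {
  const int R = A.n_rows;
  const int nbin = U.n_rows;
  const int nu = U.n_cols;
  const int T = sample_bins.n_elem;

  mat out(T, R, fill::zeros);
  vec x(R, fill::zeros);
  vec s(R, fill::zeros), f(R, fill::ones), v(R, fill::ones), q(R, fill::ones);

  mat E(R, R), Eh(R, R);
  vec rfull(R, fill::zeros), rhalf(R, fill::zeros);
  rowvec uprev(nu);
  uprev.fill(datum::nan);

  // BOLD observation coefficients (1.5 T convention): k1 = 7 E0, k2 = 2,
  // k3 = 2 E0 - 0.2; output in percent signal change.
  vec k1(R), k3(R);
  for (int r = 0; r < R; ++r) {
    k1(r) = 7.0 * hemo(r, 4);
    k3(r) = 2.0 * hemo(r, 4) - 0.2;
  }
  const double k2 = 2.0;

  auto observe = [&](int t) {
    for (int r = 0; r < R; ++r)
      out(t, r) = 100.0 * V0 *
                  (k1(r) * (1.0 - q(r)) + k2 * (1.0 - q(r) / v(r)) +
                   k3(r) * (1.0 - v(r)));
  };

  int next_sample = 0;
  // sample_bins are 0-based bin indices: bin b samples the state *before*
  // integrating bin b, i.e. at time b*dt.
  while (next_sample < T && sample_bins(next_sample) == 0) {
    observe(next_sample);
    ++next_sample;
  }

  for (int i = 0; i < nbin; ++i) {
    rowvec u = U.row(i);
    if (any(u != uprev) || uprev.has_nan()) {
      mat M = A;
      for (int j = 0; j < nu; ++j)
        if (u(j) != 0.0) M += u(j) * B.slice(j);
      E = expmat(M * dt);
      Eh = expmat(M * (dt / 2.0));
      vec cu = C * u.t();
      if (norm(cu, 2) > 0.0) {
        rfull = solve(M, (E - eye(R, R)) * cu);
        rhalf = solve(M, (Eh - eye(R, R)) * cu);
      } else {
        rfull.zeros();
        rhalf.zeros();
      }
      uprev = u;
    }
    vec xa = x;
    vec xm = Eh * x + rhalf;
    vec xb = E * x + rfull;
    hemo_rk4(xa, xm, xb, s, f, v, q, hemo, dt);
    x = xb;
    if (v.min() <= 0.0 || q.min() <= 0.0 || f.min() <= 0.0)
      Rcpp::stop("hemodynamic state became non-positive at bin %d", i + 1);
    while (next_sample < T && (int)sample_bins(next_sample) == i + 1) {
      observe(next_sample);
      ++next_sample;
    }
  }
  return out;
}
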