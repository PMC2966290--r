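// Iterative soft-thresholding solver for the naive elastic net
//   f(w) = (1/n) ||y - X w||^2 + mu ||w||^2 + tau ||w||_1
// Proximal gradient (ISTA) with optional Nesterov acceleration; the
// accelerated path keeps a monotone safeguard so the objective trace is
// non-increasing in both modes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec soft(const vec& v, double t) {
  return sign(v) % clamp(abs(v) - t, 0.0, datum::inf);
}

static inline double objective(const mat& X, const vec& y, const vec& w,
                               double mu, double tau, double n) {
  vec r = y - X * w;
  return dot(r, r) / n + mu * dot(w, w) + tau * norm(w, 1);
}

// Largest eigenvalue of (2/n) X'X + 2 mu I by power iteration on X'X.
// [[Rcpp::export]]
double lipschitz_constant(const arma::mat& X, double mu,
                          int iter = 100, double tol = 1e-7) {
  const double n = static_cast<double>(X.n_rows);
  vec v(X.n_cols, fill::ones);
  v /= norm(v);
  double lam = 0.0, lam_old = 0.0;
  for (int i = 0; i < iter; ++i) {
    vec u = X.t() * (X * v);
    lam = norm(u);
    if (lam < datum::eps) return 2.0 * mu + datum::eps;  // X'X == 0
    v = u / lam;
    if (i > 0 && std::abs(lam - lam_old) <= tol * lam) break;
    lam_old = lam;
  }
  return 2.0 * lam / n + 2.0 * mu;
}

// [[Rcpp::export]]
Rcpp::List l1l2_ista(const arma::mat& X, const arma::vec& y,
                     double mu, double tau,
                     double step, double tol, int max_iter,
                     bool accelerate, bool keep_trace,
                     const arma::vec& w_init) {
  const double n = static_cast<double>(X.n_rows);
  const double thr = step * tau;  // prox of tau||w||_1 with step s is soft(., s*tau)
  // gradient of smooth part: (2/n) X'(Xw - y) + 2 mu w

  vec w = w_init;
  vec z = w;            // extrapolation point (FISTA)
  double t_k = 1.0;
  double f_cur = objective(X, y, w, mu, tau, n);

  std::vector<double> trace;
  if (keep_trace) trace.push_back(f_cur);

  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    const vec& point = accelerate ? z : w;
    vec grad = (2.0 / n) * (X.t() * (X * point - y)) + 2.0 * mu * point;
    vec w_new = soft(point - step * grad, thr);

    if (accelerate) {
      double f_new = objective(X, y, w_new, mu, tau, n);
      if (f_new > f_cur) {
        // safeguard: plain ISTA step from the last iterate, restart momentum
        grad = (2.0 / n) * (X.t() * (X * w - y)) + 2.0 * mu * w;
        w_new = soft(w - step * grad, thr);
        f_new = objective(X, y, w_new, mu, tau, n);
        t_k = 1.0;
      }
      double t_next = (1.0 + std::sqrt(1.0 + 4.0 * t_k * t_k)) / 2.0;
      z = w_new + ((t_k - 1.0) / t_next) * (w_new - w);
      t_k = t_next;
      f_cur = f_new;
    } else {
      f_cur = objective(X, y, w_new, mu, tau, n);
    }

    double rel = norm(w_new - w) / std::max(norm(w), 1e-10);
    bool done = rel < tol;
    w = w_new;
    if (keep_trace) trace.push_back(f_cur);
    if (done) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("w") = w,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("objective") = f_cur);
  if (keep_trace) out["trace"] = trace;
  return out;
}
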