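// Hot numerical kernels for the equal-weight Gaussian mixture marginals:
// cdf/pdf evaluation, quantile inversion (safeguarded Newton), and the
// fused Monte-Carlo objective + gradient of the marginal update.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT_2PI = 0.3989422804014326779;

static inline double norm_cdf(double t) { return 0.5 * std::erfc(-t * INV_SQRT2); }
static inline double norm_pdf(double t) { return INV_SQRT_2PI * std::exp(-0.5 * t * t); }

// [[Rcpp::export]]
List mix_eval_cpp(NumericVector x, NumericVector means, double sigma) {
  const int n = x.size(), g = means.size();
  NumericVector P(n), f(n);
  const double inv_s = 1.0 / sigma, inv_g = 1.0 / g;
  for (int i = 0; i < n; ++i) {
    double sp = 0.0, sd = 0.0;
    for (int k = 0; k < g; ++k) {
      double t = (x[i] - means[k]) * inv_s;
      sp += norm_cdf(t);
      sd += norm_pdf(t);
    }
    P[i] = sp * inv_g;
    f[i] = sd * inv_g * inv_s;
  }
  return List::create(_["cdf"] = P, _["pdf"] = f);
}

// [[Rcpp::export]]
NumericVector mix_quantile_cpp(NumericVector u, NumericVector means, double sigma) {
  const int n = u.size(), g = means.size();
  NumericVector out(n);
  double mn = means[0], mx = means[0];
  for (int k = 1; k < g; ++k) {
    if (means[k] < mn) mn = means[k];
    if (means[k] > mx) mx = means[k];
  }
  const double inv_s = 1.0 / sigma, inv_g = 1.0 / g;
  for (int i = 0; i < n; ++i) {
    // the quantile lies in [min(means), max(means)] + sigma * qnorm(u)
    double q = R::qnorm(u[i], 0.0, 1.0, 1, 0);
    double lo = mn + sigma * q, hi = mx + sigma * q;
    double x = 0.5 * (lo + hi);
    for (int it = 0; it < 100; ++it) {
      double sp = 0.0, sd = 0.0;
      for (int k = 0; k < g; ++k) {
        double t = (x - means[k]) * inv_s;
        sp += norm_cdf(t);
        sd += norm_pdf(t);
      }
      double r = sp * inv_g - u[i];
      if (std::fabs(r) < 1e-15 || (hi - lo) < 1e-14 * (1.0 + std::fabs(x))) break;
      if (r < 0) lo = x; else hi = x;
      double xn = x - r / std::max(sd * inv_g * inv_s, 1e-300);
      if (!std::isfinite(xn) || xn <= lo || xn >= hi) xn = 0.5 * (lo + hi);
      x = xn;
    }
    out[i] = x;
  }
  return out;
}

// Monte-Carlo completed-data objective for the mixture means and its
// gradient, in one pass:
//   value = sum_i w_i * ( -1/2 z_i' (K - I) z_i + sum_j log f_j(x_ij) )
// with z_ij = qnorm(F_j(x_ij)) clipped away from 0/1 (the latent
// transform is saturated there, so the chain-rule term is frozen).
// [[Rcpp::export]]
List theta_obj_grad_cpp(NumericMatrix X, NumericVector w, NumericMatrix K,
                        NumericVector sigmas, NumericMatrix Th,
                        double eps = 1e-10) {
  const int n = X.nrow(), p = X.ncol(), g = Th.nrow();
  const double inv_g = 1.0 / g;
  NumericMatrix Z(n, p), rmD(n, p);
  LogicalMatrix clipped(n, p);
  std::vector<double> D((size_t)n * g * p);   // dnorm(t) per column
  std::vector<double> Tm((size_t)n * g * p);  // t per column
  NumericVector logf(n);

  for (int j = 0; j < p; ++j) {
    const double inv_s = 1.0 / sigmas[j];
    for (int i = 0; i < n; ++i) {
      double sp = 0.0, sd = 0.0;
      size_t base = ((size_t)j * n + i) * g;
      for (int k = 0; k < g; ++k) {
        double t = (X(i, j) - Th(k, j)) * inv_s;
        double d = norm_pdf(t);
        Tm[base + k] = t;
        D[base + k] = d;
        sp += norm_cdf(t);
        sd += d;
      }
      double P = sp * inv_g;
      bool cl = (P < eps) || (P > 1.0 - eps);
      if (P < eps) P = eps;
      if (P > 1.0 - eps) P = 1.0 - eps;
      clipped(i, j) = cl;
      Z(i, j) = R::qnorm(P, 0.0, 1.0, 1, 0);
      double rm = sd * inv_g;
      rmD(i, j) = rm;
      logf[i] += std::log(std::max(rm * inv_s, 1e-300));
    }
  }

  // G = Z (K - I); quadratic form per row
  NumericMatrix G(n, p);
  double value = 0.0;
  for (int i = 0; i < n; ++i) {
    double quad = 0.0;
    for (int j = 0; j < p; ++j) {
      double acc = 0.0;
      for (int l = 0; l < p; ++l) {
        double klj = K(l, j) - (l == j ? 1.0 : 0.0);
        acc += Z(i, l) * klj;
      }
      G(i, j) = acc;
      quad += acc * Z(i, j);
    }
    value += w[i] * (-0.5 * quad + logf[i]);
  }

  NumericMatrix grad(g, p);
  for (int j = 0; j < p; ++j) {
    const double inv_s = 1.0 / sigmas[j];
    for (int i = 0; i < n; ++i) {
      size_t base = ((size_t)j * n + i) * g;
      double phi_z = std::max(norm_pdf(Z(i, j)), 1e-300);
      double a = clipped(i, j) ? 0.0
        : w[i] * G(i, j) * inv_g * inv_s / phi_z;      // -G * dz/dtheta
      double b = w[i] * inv_g * inv_s / std::max(rmD(i, j), 1e-300);
      for (int k = 0; k < g; ++k) {
        double d = D[base + k];
        grad(k, j) += a * d + b * d * Tm[base + k];
      }
    }
  }
  return List::create(_["value"] = value, _["grad"] = grad);
}
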