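// Marginal likelihood of a random-intercept model for twin pairs with
// zygosity-specific intercept variances, integrated by adaptive
// Gauss-Hermite quadrature centered at each pair's conditional mode.
//
// Families: 0 = Bernoulli with logit link, 1 = Bernoulli with log link,
// 2 = Gaussian with identity link (residual sd = scale).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log f(y | eta + u) summed over members of one pair, plus derivatives in u
static void pair_loglik(const double* eta, const double* y, int len,
                        double u, int family, double scale,
                        double& ll, double& d1, double& d2) {
  ll = 0.0; d1 = 0.0; d2 = 0.0;
  for (int i = 0; i < len; ++i) {
    double lp = eta[i] + u;
    if (family == 0) {            // Bernoulli-logit
      double p = 1.0 / (1.0 + std::exp(-lp));
      ll += y[i] * lp - softplus(lp);
      d1 += y[i] - p;
      d2 -= p * (1.0 - p);
    } else if (family == 1) {     // Bernoulli-log (lp = log mu, mu < 1)
      if (lp > -1e-8) lp = -1e-8;
      double mu = std::exp(lp);
      if (y[i] > 0.5) {
        ll += lp; // d1 += 0 (d log mu / du = 1 => y * lp derivative is 1)
        d1 += 1.0;
      } else {
        double om = 1.0 - mu;
        ll += std::log(om);
        d1 -= mu / om;
        d2 -= mu / (om * om);
      }
    } else {                      // Gaussian-identity
      double r = y[i] - lp;
      double s2 = scale * scale;
      ll += -0.5 * std::log(2.0 * M_PI * s2) - 0.5 * r * r / s2;
      d1 += r / s2;
      d2 -= 1.0 / s2;
    }
  }
}

// [[Rcpp::export]]
double cpp_aghq_loglik(NumericVector beta, double s2_mz, double s2_dz,
                       NumericMatrix X, NumericVector y,
                       IntegerVector pair_start, IntegerVector pair_len,
                       IntegerVector pair_dz,
                       NumericVector gh_x, NumericVector gh_w,
                       int family, double scale) {
  const int n = X.nrow(), p = X.ncol(), J = pair_start.size();
  const int K = gh_x.size();
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double b = beta[j];
    if (b == 0.0) continue;
    const double* xc = &X(0, j);
    for (int i = 0; i < n; ++i) eta[i] += b * xc[i];
  }
  std::vector<double> logw(K);
  for (int k = 0; k < K; ++k) logw[k] = std::log(gh_w[k]) + gh_x[k] * gh_x[k];

  const double* yp = y.begin();
  double total = 0.0;
  for (int jp = 0; jp < J; ++jp) {
    const int st = pair_start[jp], len = pair_len[jp];
    const double s2 = pair_dz[jp] ? s2_dz : s2_mz;
    const double* ej = &eta[st];
    const double* yj = yp + st;
    double ll, d1, d2;
    if (s2 < 1e-12) {             // integral collapses to u = 0
      pair_loglik(ej, yj, len, 0.0, family, scale, ll, d1, d2);
      total += ll;
      continue;
    }
    // conditional mode of log f(y|u) - u^2/(2 s2) by damped Newton
    double u = 0.0;
    for (int it = 0; it < 100; ++it) {
      pair_loglik(ej, yj, len, u, family, scale, ll, d1, d2);
      double g = d1 - u / s2;
      double h = d2 - 1.0 / s2;   // h < 0 always
      double step = -g / h;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      u += step;
      if (std::fabs(g) < 1e-10 && std::fabs(step) < 1e-8) break;
    }
    pair_loglik(ej, yj, len, u, family, scale, ll, d1, d2);
    double h = d2 - 1.0 / s2;
    double sd_hat = 1.0 / std::sqrt(-h);
    // log integral = logsumexp_k [ log w_k + x_k^2 + log f(u_k) +
    //                log phi(u_k; 0, s2) ] + log(sqrt(2) sd_hat)
    double maxterm = -INFINITY;
    std::vector<double> terms(K);
    for (int k = 0; k < K; ++k) {
      double uk = u + M_SQRT2 * sd_hat * gh_x[k];
      pair_loglik(ej, yj, len, uk, family, scale, ll, d1, d2);
      double lphi = -0.5 * std::log(2.0 * M_PI * s2) - 0.5 * uk * uk / s2;
      terms[k] = logw[k] + ll + lphi;
      if (terms[k] > maxterm) maxterm = terms[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(terms[k] - maxterm);
    total += maxterm + std::log(s) + 0.5 * std::log(2.0) + std::log(sd_hat);
  }
  return total;
}

// Marginal log-likelihood plus its score, via Fisher's identity:
// d l_j / d theta = E_{u | y_j} [ d log f(y_j, u | theta) / d theta ],
// with the posterior expectation taken over the same adaptive nodes.
// Returns list(loglik, grad) where grad is ordered as
// (beta, d/d log s2_mz, d/d log s2_dz, d/d log scale).
// [[Rcpp::export]]
List cpp_aghq_score(NumericVector beta, double s2_mz, double s2_dz,
                    NumericMatrix X, NumericVector y,
                    IntegerVector pair_start, IntegerVector pair_len,
                    IntegerVector pair_dz,
                    NumericVector gh_x, NumericVector gh_w,
                    int family, double scale) {
  const int n = X.nrow(), p = X.ncol(), J = pair_start.size();
  const int K = gh_x.size();
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double b = beta[j];
    if (b == 0.0) continue;
    const double* xc = &X(0, j);
    for (int i = 0; i < n; ++i) eta[i] += b * xc[i];
  }
  std::vector<double> logw(K);
  for (int k = 0; k < K; ++k) logw[k] = std::log(gh_w[k]) + gh_x[k] * gh_x[k];

  const double* yp = y.begin();
  double total = 0.0;
  NumericVector gbeta(p);
  double g_ls2_mz = 0.0, g_ls2_dz = 0.0, g_lscale = 0.0;
  std::vector<double> terms(K), node_u(K);
  std::vector<double> d1i(2);   // per-member d log f / d eta at a node

  for (int jp = 0; jp < J; ++jp) {
    const int st = pair_start[jp], len = pair_len[jp];
    const bool dz = pair_dz[jp] != 0;
    const double s2 = dz ? s2_dz : s2_mz;
    const double* ej = &eta[st];
    const double* yj = yp + st;
    double ll, d1, d2;

    if (s2 < 1e-12) {
      pair_loglik(ej, yj, len, 0.0, family, scale, ll, d1, d2);
      total += ll;
      for (int i = 0; i < len; ++i) {
        double lp = ej[i], di;
        if (family == 0) di = yj[i] - 1.0 / (1.0 + std::exp(-lp));
        else if (family == 1) {
          if (lp > -1e-8) lp = -1e-8;
          double mu = std::exp(lp);
          di = (yj[i] > 0.5) ? 1.0 : -mu / (1.0 - mu);
        } else {
          di = (yj[i] - lp) / (scale * scale);
          g_lscale += (yj[i] - lp) * (yj[i] - lp) / (scale * scale) - 1.0;
        }
        for (int j = 0; j < p; ++j) gbeta[j] += di * X(st + i, j);
      }
      continue;
    }

    double u = 0.0;
    for (int it = 0; it < 100; ++it) {
      pair_loglik(ej, yj, len, u, family, scale, ll, d1, d2);
      double g = d1 - u / s2;
      double h = d2 - 1.0 / s2;
      double step = -g / h;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      u += step;
      if (std::fabs(g) < 1e-10 && std::fabs(step) < 1e-8) break;
    }
    pair_loglik(ej, yj, len, u, family, scale, ll, d1, d2);
    double h = d2 - 1.0 / s2;
    double sd_hat = 1.0 / std::sqrt(-h);

    double maxterm = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double uk = u + M_SQRT2 * sd_hat * gh_x[k];
      node_u[k] = uk;
      pair_loglik(ej, yj, len, uk, family, scale, ll, d1, d2);
      double lphi = -0.5 * std::log(2.0 * M_PI * s2) - 0.5 * uk * uk / s2;
      terms[k] = logw[k] + ll + lphi;
      if (terms[k] > maxterm) maxterm = terms[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) { terms[k] = std::exp(terms[k] - maxterm); s += terms[k]; }
    total += maxterm + std::log(s) + 0.5 * std::log(2.0) + std::log(sd_hat);

    double g_var = 0.0;
    for (int k = 0; k < K; ++k) {
      const double w = terms[k] / s;     // posterior node weight
      const double uk = node_u[k];
      g_var += w * 0.5 * (uk * uk / s2 - 1.0);
      for (int i = 0; i < len; ++i) {
        double lp = ej[i] + uk, di;
        if (family == 0) di = yj[i] - 1.0 / (1.0 + std::exp(-lp));
        else if (family == 1) {
          if (lp > -1e-8) lp = -1e-8;
          double mu = std::exp(lp);
          di = (yj[i] > 0.5) ? 1.0 : -mu / (1.0 - mu);
        } else {
          di = (yj[i] - lp) / (scale * scale);
          g_lscale += w * ((yj[i] - lp) * (yj[i] - lp) / (scale * scale) - 1.0);
        }
        for (int j = 0; j < p; ++j) gbeta[j] += w * di * X(st + i, j);
      }
    }
    if (dz) g_ls2_dz += g_var; else g_ls2_mz += g_var;
  }
  return List::create(_["loglik"] = total, _["gbeta"] = gbeta,
                      _["g_ls2_mz"] = g_ls2_mz, _["g_ls2_dz"] = g_ls2_dz,
                      _["g_lscale"] = g_lscale);
}
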