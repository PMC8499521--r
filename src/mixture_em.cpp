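#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Constrained two-component Gaussian mixture for reverse-regression
// coefficients: (1 - pi) N(0, s2n) + pi N(mu, s2a), with the null mean fixed
// at 0 and, after every M-step, s2n clamped above v/10 and s2a above k*v.
// Clamping is the box-constrained argmax of the M-step objective, so the
// generalised-EM ascent property is preserved.

static const double LOG2PI = 1.837877066409345483560659472811;

static inline double log_dnorm(double x, double mu, double s2) {
  double z = x - mu;
  return -0.5 * (LOG2PI + std::log(s2) + z * z / s2);
}

struct EmResult {
  double pi, mu, s2n, s2a, loglik;
  bool converged;
  int iter;
  std::vector<double> trace;
};

static EmResult em_fit(const double* beta, int M, double v, double kfac,
                       int maxit, double tol, bool keep_trace) {
  EmResult res;
  res.converged = false;
  res.iter = 0;

  const double s2n_min = v / 10.0 * 1.0000001;
  const double s2a_min = kfac * v * 1.0000001;

  // degenerate input: all betas identical
  double bmin = beta[0], bmax = beta[0];
  for (int i = 1; i < M; ++i) {
    if (beta[i] < bmin) bmin = beta[i];
    if (beta[i] > bmax) bmax = beta[i];
  }
  if (!(bmax > bmin)) {
    res.pi = 0.0; res.mu = beta[0];
    res.s2n = std::max(v, s2n_min);
    res.s2a = std::max(kfac * v * 1.01, s2a_min);
    res.loglik = NA_REAL;
    return res;
  }

  // init: pi = 0.05; mu, s2a from the 5% largest |beta|
  int ntop = std::max(1, (int)std::floor(0.05 * M));
  std::vector<double> absb(M);
  for (int i = 0; i < M; ++i) absb[i] = std::fabs(beta[i]);
  std::vector<double> sorted(absb);
  std::nth_element(sorted.begin(), sorted.end() - ntop, sorted.end());
  double cut = sorted[M - ntop];
  double top_sum = 0.0, top_ss = 0.0;
  int top_n = 0;
  for (int i = 0; i < M && top_n < ntop; ++i) {
    if (absb[i] >= cut) {
      top_sum += beta[i];
      top_ss += beta[i] * beta[i];
      ++top_n;
    }
  }
  double pi = 0.05;
  double mu = top_sum / top_n;
  double top_var = top_n > 1 ? (top_ss - top_sum * top_sum / top_n) / (top_n - 1) : 0.0;
  double s2n = std::max(v, s2n_min);
  double s2a = std::max(top_var, 1.01 * kfac * v);

  std::vector<double> r(M);
  double prev_ll = R_NegInf;

  for (int it = 0; it < maxit; ++it) {
    // E-step (log space) + loglik
    double pic = std::min(std::max(pi, 1e-300), 1.0 - 1e-16);
    double lpi1 = std::log(pic), lpi0 = std::log1p(-pic);
    double ll = 0.0;
    double sum_r = 0.0, sum_rb = 0.0;
    for (int i = 0; i < M; ++i) {
      double la = lpi1 + log_dnorm(beta[i], mu, s2a);
      double l0 = lpi0 + log_dnorm(beta[i], 0.0, s2n);
      double mx = la > l0 ? la : l0;
      double denom = std::exp(la - mx) + std::exp(l0 - mx);
      ll += mx + std::log(denom);
      double ri = std::exp(la - mx) / denom;
      r[i] = ri;
      sum_r += ri;
      sum_rb += ri * beta[i];
    }
    res.iter = it + 1;
    if (keep_trace) res.trace.push_back(ll);
    if (it > 0 && std::fabs(ll - prev_ll) <=
        tol * (std::fabs(prev_ll) + 1e-300)) {
      res.loglik = ll;
      res.converged = true;
      prev_ll = ll;
      break;
    }
    prev_ll = ll;
    res.loglik = ll;

    // M-step with box constraints
    pi = sum_r / M;
    double mu_new = sum_r > 1e-300 ? sum_rb / sum_r : mu;
    double ss_a = 0.0, ss_n = 0.0, sum_1r = 0.0;
    for (int i = 0; i < M; ++i) {
      double da = beta[i] - mu_new;
      ss_a += r[i] * da * da;
      ss_n += (1.0 - r[i]) * beta[i] * beta[i];
      sum_1r += 1.0 - r[i];
    }
    mu = mu_new;
    s2a = sum_r > 1e-300 ? ss_a / sum_r : s2a;
    s2n = sum_1r > 1e-300 ? ss_n / sum_1r : s2n;
    if (s2n < s2n_min) s2n = s2n_min;
    if (s2a < s2a_min) s2a = s2a_min;
  }

  res.pi = pi; res.mu = mu; res.s2n = s2n; res.s2a = s2a;
  return res;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector beta, double v, double kfac = 100.0,
                int maxit = 500, double tol = 1e-8) {
  EmResult r = em_fit(beta.begin(), beta.size(), v, kfac, maxit, tol, true);
  return List::create(
    _["pi_alt"] = r.pi,
    _["mu_alt"] = r.mu,
    _["sigma2_null"] = r.s2n,
    _["sigma2_alt"] = r.s2a,
    _["loglik"] = r.loglik,
    _["trace"] = NumericVector(r.trace.begin(), r.trace.end()),
    _["converged"] = r.converged,
    _["iterations"] = r.iter
  );
}

// Batch: for each row of `betas`, refit the mixture and compute the region
// summaries L_h (scale-weighted evidence), p_h (horizontal proportion) and
// p_v (vertical proportion). `wh` are the 1/2^s scale weights, `wv` the
// sub-region membership weights, `thr` the per-coefficient posterior
// thresholds 1 / (sqrt(2 log K) sqrt(2^s)).
// [[Rcpp::export(name = ".em_batch_stats_cpp")]]
NumericMatrix em_batch_stats_cpp(NumericMatrix betas, NumericVector v,
                                 NumericVector wh, NumericVector wv,
                                 NumericVector thr, double kfac = 100.0,
                                 int maxit = 500, double tol = 1e-8) {
  int n = betas.nrow(), M = betas.ncol();
  if (wh.size() != M || wv.size() != M || thr.size() != M)
    stop("weight vectors must match the number of coefficients");
  if (v.size() != 1 && v.size() != n)
    stop("v must be a scalar or one value per row");
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("Lh", "ph", "pv", "pi_alt", "converged");
  std::vector<double> row(M);
  for (int i = 0; i < n; ++i) {
    double vi = v.size() == 1 ? v[0] : v[i];
    for (int j = 0; j < M; ++j) row[j] = betas(i, j);
    EmResult f = em_fit(row.data(), M, vi, kfac, maxit, tol, false);
    double pic = std::min(std::max(f.pi, 0.0), 1.0);
    double Lh = 0.0, ph = 0.0, pv = 0.0;
    for (int j = 0; j < M; ++j) {
      double lda = log_dnorm(row[j], f.mu, f.s2a);
      double ld0 = log_dnorm(row[j], 0.0, f.s2n);
      double pihat;
      if (pic <= 0.0) {
        pihat = 0.0;
      } else if (pic >= 1.0) {
        pihat = 1.0;
      } else {
        double la = std::log(pic) + lda;
        double l0 = std::log1p(-pic) + ld0;
        double mx = la > l0 ? la : l0;
        pihat = std::exp(la - mx) / (std::exp(la - mx) + std::exp(l0 - mx));
      }
      double pit = pihat - thr[j];
      if (pit < 0.0) pit = 0.0;
      Lh += wh[j] * (pit * std::exp(lda) - (1.0 - pit) * std::exp(ld0));
      ph += wh[j] * pit;
      pv += wv[j] * pit;
    }
    out(i, 0) = Lh; out(i, 1) = ph; out(i, 2) = pv;
    out(i, 3) = pic; out(i, 4) = f.converged ? 1.0 : 0.0;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
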