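#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a valid-trial choice sequence under one of the
// bandit learning models. Mirrors the R reference implementation in
// R/models.R (run_model); tests assert agreement to 1e-10.
//
// model codes: 1 = rw1, 2 = rw2, 3 = kf, 4 = vkf (V+U softmax),
//              5 = vkf_rv (V-only softmax)
// params are passed in registry order:
//   rw1: alpha, beta_v
//   rw2: alpha_pos, alpha_neg, beta_v
//   kf : v, sigma2, beta_v
//   vkf: lambda, v0, sigma2, beta_v, beta_u
//   vkf_rv: lambda, v0, sigma2, beta_v
// w0 < 0 means "use the model default" (v for kf, v0 for vkf).

static double softmax_logp(const std::vector<double>& z, int pick) {
  double zmax = z[0];
  for (size_t j = 1; j < z.size(); ++j) if (z[j] > zmax) zmax = z[j];
  double denom = 0.0;
  for (size_t j = 0; j < z.size(); ++j) denom += std::exp(z[j] - zmax);
  return (z[pick] - zmax) - std::log(denom);
}

// [[Rcpp::export]]
double nll_cpp(IntegerVector choice, NumericVector outcome, int model,
               NumericVector params, int n_arms, double m0, double w0) {
  const int n = choice.size();
  std::vector<double> m(n_arms, m0), w(n_arms, 0.0), v(n_arms, 0.0);
  std::vector<double> z(n_arms);
  double beta_v = 0.0, beta_u = 0.0;
  double alpha = 0.0, alpha_pos = 0.0, alpha_neg = 0.0;
  double vproc = 0.0, sigma2 = 0.0, lambda = 0.0;

  switch (model) {
  case 1:
    alpha = params[0]; beta_v = params[1];
    break;
  case 2:
    alpha_pos = params[0]; alpha_neg = params[1]; beta_v = params[2];
    break;
  case 3:
    vproc = params[0]; sigma2 = params[1]; beta_v = params[2];
    std::fill(w.begin(), w.end(), w0 < 0 ? vproc : w0);
    break;
  case 4:
  case 5:
    lambda = params[0]; sigma2 = params[2]; beta_v = params[3];
    if (model == 4) beta_u = params[4];
    std::fill(v.begin(), v.end(), params[1]);
    std::fill(w.begin(), w.end(), w0 < 0 ? params[1] : w0);
    break;
  default:
    stop("unknown model code");
  }

  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int c = choice[t] - 1;
    const double o = outcome[t];
    if (c < 0 || c >= n_arms) stop("choice index out of range");

    // policy from prior (pre-choice) state
    if (model <= 2) {
      for (int j = 0; j < n_arms; ++j) z[j] = beta_v * m[j];
    } else {
      // floor mirrors the R policy guard against underflow at extreme gains
      double sm = 0.0, sw = 0.0;
      for (int j = 0; j < n_arms; ++j) {
        sm += std::max(m[j], 1e-12);
        sw += std::max(w[j], 1e-12);
      }
      for (int j = 0; j < n_arms; ++j)
        z[j] = beta_v * (std::max(m[j], 1e-12) / sm) +
               beta_u * (std::max(w[j], 1e-12) / sw);
    }
    nll -= softmax_logp(z, c);

    // state update
    if (model == 1) {
      m[c] += alpha * (o - m[c]);
    } else if (model == 2) {
      m[c] += (o == 1.0 ? alpha_pos : alpha_neg) * (o - m[c]);
    } else if (model == 3) {
      const double k = (w[c] + vproc) / (w[c] + vproc + sigma2);
      m[c] += k * (o - m[c]);
      const double wc = std::max((1.0 - k) * (w[c] + vproc), 1e-12);
      for (int j = 0; j < n_arms; ++j) w[j] += vproc;
      w[c] = wc;
    } else {
      const double k = (w[c] + v[c]) / (w[c] + v[c] + sigma2);
      const double m_new = m[c] + k * (o - m[c]);
      const double w_new = std::max((1.0 - k) * (w[c] + v[c]), 1e-12);
      const double w_cov = (1.0 - k) * w[c];
      // floor mirrors the R update guard against multiplicative underflow
      const double v_new = std::max(v[c] + lambda *
        ((m_new - m[c]) * (m_new - m[c]) + w[c] + w_new - 2.0 * w_cov - v[c]),
        1e-12);
      for (int j = 0; j < n_arms; ++j) w[j] += v[j];
      m[c] = m_new; w[c] = w_new; v[c] = v_new;
    }
  }
  return nll;
}
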