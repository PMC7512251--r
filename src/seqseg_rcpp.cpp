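#include <Rcpp.h>
using namespace Rcpp;

// Log of the full (sigma0, delta) posterior for two zero-mean segments:
// Laplace(1, beta) prior on the variance ratio delta, Jeffreys 1/sigma0 on
// the base scale. Constant convention: includes the Gaussian -(n/2)log(2*pi)
// and the Laplace -log(beta); the improper Jeffreys prior carries none.
static inline double lp_full(double s, double d,
                             double n1, double ss1,
                             double n2, double ss2, double beta) {
  return -0.5 * (n1 + n2) * std::log(2.0 * M_PI)
         - std::fabs(d - 1.0) / beta - std::log(beta)
         - (n1 + n2 + 1.0) * std::log(s)
         - 0.5 * n2 * std::log(d)
         - ss1 / (2.0 * s * s)
         - ss2 / (2.0 * d * s * s);
}

// [[Rcpp::export]]
double log_full_posterior_cpp(double sigma0, double delta,
                              double n1, double ss1,
                              double n2, double ss2, double beta) {
  return lp_full(sigma0, delta, n1, ss1, n2, ss2, beta);
}

// Block Metropolis-Hastings on (sigma0, delta): each iteration updates
// sigma0 then delta, proposing from an exponential distribution with mean at
// the current value (q(x'|x) = (1/x) exp(-x'/x)) with the Hastings
// correction. Uses R's RNG, so set.seed() on the R side governs the chain.
// [[Rcpp::export]]
List mh_sample_cpp(double n1, double ss1, double n2, double ss2, double beta,
                   int n_samples, int n_burn,
                   double init_sigma0, double init_delta) {
  RNGScope scope;
  NumericVector sigma0(n_samples), delta(n_samples), lp_draw(n_samples);
  double s = init_sigma0, d = init_delta;
  double lp = lp_full(s, d, n1, ss1, n2, ss2, beta);
  long acc_s = 0, acc_d = 0;
  const int total = n_samples + n_burn;

  for (int i = 0; i < total; i++) {
    // sigma0 block
    double sp = s * exp_rand();
    double lpp = lp_full(sp, d, n1, ss1, n2, ss2, beta);
    double la = lpp - lp + (-std::log(sp) - s / sp) - (-std::log(s) - sp / s);
    if (std::log(unif_rand()) < la) { s = sp; lp = lpp; acc_s++; }
    // delta block
    double dp = d * exp_rand();
    lpp = lp_full(s, dp, n1, ss1, n2, ss2, beta);
    la = lpp - lp + (-std::log(dp) - d / dp) - (-std::log(d) - dp / d);
    if (std::log(unif_rand()) < la) { d = dp; lp = lpp; acc_d++; }

    if (i >= n_burn) {
      const int j = i - n_burn;
      sigma0[j] = s;
      delta[j] = d;
      lp_draw[j] = lp;
    }
  }

  return List::create(
    _["sigma0"] = sigma0,
    _["delta"] = delta,
    _["log_post"] = lp_draw,
    _["accept_sigma0"] = (double)acc_s / total,
    _["accept_delta"] = (double)acc_d / total);
}

// Sliding-window minimum over truncated one-sided windows: for each
// (1-based) evaluation index t, the minimum of y over indices j with
// j < t, t - j < k (left) and j > t, j - t < k (right). Empty windows
// return NA.
// [[Rcpp::export]]
List window_min_cpp(NumericVector y, IntegerVector idx, int k) {
  const int n = y.size(), m = idx.size();
  NumericVector left(m), right(m);
  for (int i = 0; i < m; i++) {
    const int t = idx[i];            // 1-based
    double lmin = R_PosInf, rmin = R_PosInf;
    const int l0 = std::max(1, t - k + 1);
    for (int j = l0; j <= t - 1; j++) lmin = std::min(lmin, y[j - 1]);
    const int r1 = std::min(n, t + k - 1);
    for (int j = t + 1; j <= r1; j++) rmin = std::min(rmin, y[j - 1]);
    left[i] = (t - 1 >= l0) ? lmin : NA_REAL;
    right[i] = (r1 >= t + 1) ? rmin : NA_REAL;
  }
  return List::create(_["left"] = left, _["right"] = right);
}
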