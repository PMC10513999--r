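#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Single-site conditional activation probability in spin coding:
// P(s_i = +1 | rest) = 1 / (1 + exp(-2 * beta * (sum_j w_ij s_j + tau_i + e)))
static inline double p_up(const NumericMatrix& w, const NumericVector& tau,
                          const std::vector<int>& s, int i, double e,
                          double beta, int n) {
  double h = tau[i] + e;
  for (int j = 0; j < n; ++j) h += w(j, i) * s[j];
  return 1.0 / (1.0 + std::exp(-2.0 * beta * h));
}

// One sweep = n single-site Glauber updates. random_order picks each update
// site uniformly at random (random-sequential scheme); otherwise sites are
// visited in fixed cyclic order 0..n-1. Uses R's RNG for reproducibility.
static void do_sweep(std::vector<int>& s, const NumericMatrix& w,
                     const NumericVector& tau, double e, double beta,
                     bool random_order, int n) {
  for (int u = 0; u < n; ++u) {
    int i = random_order ? (int)(unif_rand() * n) : u;
    if (i >= n) i = n - 1;
    double p = p_up(w, tau, s, i, e, beta, n);
    s[i] = (unif_rand() < p) ? 1 : -1;
  }
}

// [[Rcpp::export]]
IntegerVector glauber_sweep_cpp(const NumericMatrix& w, const NumericVector& tau,
                                double field, double beta, IntegerVector state,
                                bool random_order) {
  int n = w.ncol();
  std::vector<int> s(state.begin(), state.end());
  do_sweep(s, w, tau, field, beta, random_order, n);
  return IntegerVector(s.begin(), s.end());
}

// Runs `burnin` sweeps at field 0 (not recorded), then one sweep per entry of
// `field`, recording the state after each recorded sweep. Returns a
// length(field) x n matrix of spins.
// [[Rcpp::export]]
IntegerMatrix glauber_run_cpp(const NumericMatrix& w, const NumericVector& tau,
                              const NumericVector& field, double beta,
                              IntegerVector state, int burnin,
                              bool random_order) {
  int n = w.ncol();
  int nt = field.size();
  std::vector<int> s(state.begin(), state.end());
  for (int t = 0; t < burnin; ++t) do_sweep(s, w, tau, 0.0, beta, random_order, n);
  IntegerMatrix out(nt, n);
  for (int t = 0; t < nt; ++t) {
    do_sweep(s, w, tau, field[t], beta, random_order, n);
    for (int j = 0; j < n; ++j) out(t, j) = s[j];
  }
  return out;
}
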