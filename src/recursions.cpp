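#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward/backward recursions for Gaussian-emission HMMs.
//
// Two families are implemented with deliberately separate arithmetic:
//  * _raw_ variants work on the uncompressed observation sequence and
//    evaluate each Gaussian log-density pointwise;
//  * _block_ variants work on moment-summarized blocks and receive the
//    per-block log emission matrix E (computed from sum1/sum2) plus the
//    block lengths, adding (n-1) self-transitions inside each block.
// Keeping the two code paths independent lets one serve as a numerical
// cross-check of the other.

static inline double log_gauss(double x, double mean, double var) {
  return -0.5 * std::log(2.0 * M_PI * var) - (x - mean) * (x - mean) / (2.0 * var);
}

// Normalize a log-weight row into alpha[t, ] and return its log-sum.
static double normalize_row(std::vector<double>& v, NumericMatrix& alpha, int t) {
  int N = v.size();
  double m = v[0];
  for (int i = 1; i < N; ++i) if (v[i] > m) m = v[i];
  if (!R_finite(m)) stop("forward recursion degenerated: all states have zero probability");
  double s = 0.0;
  for (int i = 0; i < N; ++i) { v[i] = std::exp(v[i] - m); s += v[i]; }
  for (int i = 0; i < N; ++i) alpha(t, i) = v[i] / s;
  return m + std::log(s);
}

// [[Rcpp::export]]
List fwd_raw_cpp(NumericMatrix A, NumericVector pi, NumericVector means,
                 NumericVector vars, NumericVector obs) {
  int N = A.nrow(), T = obs.size();
  NumericMatrix alpha(T, N);
  std::vector<double> v(N);
  double ll = 0.0;
  for (int i = 0; i < N; ++i)
    v[i] = std::log(pi[i]) + log_gauss(obs[0], means[i], vars[i]);
  ll += normalize_row(v, alpha, 0);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < N; ++j) s += alpha(t - 1, j) * A(j, i);
      v[i] = std::log(s) + log_gauss(obs[t], means[i], vars[i]);
    }
    ll += normalize_row(v, alpha, t);
  }
  return List::create(_["alpha"] = alpha, _["loglik"] = ll);
}

// Scaled backward variables; row t is beta_t renormalized to sum 1.
// [[Rcpp::export]]
NumericMatrix bwd_raw_cpp(NumericMatrix A, NumericVector means,
                          NumericVector vars, NumericVector obs) {
  int N = A.nrow(), T = obs.size();
  NumericMatrix beta(T, N);
  for (int i = 0; i < N; ++i) beta(T - 1, i) = 1.0 / N;
  std::vector<double> e(N);
  for (int t = T - 2; t >= 0; --t) {
    double m = R_NegInf;
    for (int j = 0; j < N; ++j) {
      e[j] = log_gauss(obs[t + 1], means[j], vars[j]);
      if (e[j] > m) m = e[j];
    }
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      for (int j = 0; j < N; ++j)
        b += A(i, j) * std::exp(e[j] - m) * beta(t + 1, j);
      beta(t, i) = b;
      s += b;
    }
    if (s <= 0.0) stop("backward recursion degenerated");
    for (int i = 0; i < N; ++i) beta(t, i) /= s;
  }
  return beta;
}

// [[Rcpp::export]]
IntegerVector viterbi_raw_cpp(NumericMatrix A, NumericVector pi, NumericVector means,
                              NumericVector vars, NumericVector obs) {
  int N = A.nrow(), T = obs.size();
  NumericMatrix delta(T, N);
  IntegerMatrix psi(T, N);
  for (int i = 0; i < N; ++i)
    delta(0, i) = std::log(pi[i]) + log_gauss(obs[0], means[i], vars[i]);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      // ties broken toward the lowest predecessor index (strict >)
      int best = 0;
      double bv = delta(t - 1, 0) + std::log(A(0, i));
      for (int j = 1; j < N; ++j) {
        double cand = delta(t - 1, j) + std::log(A(j, i));
        if (cand > bv) { bv = cand; best = j; }
      }
      delta(t, i) = bv + log_gauss(obs[t], means[i], vars[i]);
      psi(t, i) = best;
    }
  }
  IntegerVector path(T);
  int best = 0;
  for (int i = 1; i < N; ++i) if (delta(T - 1, i) > delta(T - 1, best)) best = i;
  path[T - 1] = best;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based states
}

// Block forward recursion.  E[t, i] is the log joint emission density of all
// observations in block t under state i; n[t] is the block length.  Within a
// block the path is constrained to be constant, contributing a_ii^(n-1).
// Returns the scaled forward table, the log-likelihood of the block-constant
// path family, and the count of executed inner multiply-add operations.
// [[Rcpp::export]]
List fwd_block_cpp(NumericMatrix A, NumericVector pi, NumericMatrix E,
                   IntegerVector n) {
  int N = A.nrow(), T = E.nrow();
  NumericMatrix alpha(T, N);
  std::vector<double> v(N);
  double ll = 0.0, ops = 0.0;
  for (int i = 0; i < N; ++i) {
    double self = (n[0] > 1) ? (n[0] - 1) * std::log(A(i, i)) : 0.0;
    v[i] = std::log(pi[i]) + self + E(0, i);
  }
  ll += normalize_row(v, alpha, 0);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < N; ++j) { s += alpha(t - 1, j) * A(j, i); ops += 1.0; }
      double self = (n[t] > 1) ? (n[t] - 1) * std::log(A(i, i)) : 0.0;
      v[i] = std::log(s) + self + E(t, i);
    }
    ll += normalize_row(v, alpha, t);
  }
  return List::create(_["alpha"] = alpha, _["loglik"] = ll, _["ops"] = ops);
}

// Backward draw of one state per row of a scaled forward table.  Works for
// raw positions and for blocks alike: the last row is drawn proportional to
// alpha[T, ], and row t proportional to alpha[t, i] * A[i, s_{t+1}].
// Uses R's RNG (one uniform per row, drawn backward from the end).
// [[Rcpp::export]]
IntegerVector sample_path_cpp(NumericMatrix alpha, NumericMatrix A) {
  int T = alpha.nrow(), N = alpha.ncol();
  IntegerVector path(T);
  std::vector<double> p(N);
  for (int t = T - 1; t >= 0; --t) {
    double s = 0.0;
    if (t == T - 1) {
      for (int i = 0; i < N; ++i) { p[i] = alpha(t, i); s += p[i]; }
    } else {
      int nxt = path[t + 1] - 1;
      for (int i = 0; i < N; ++i) { p[i] = alpha(t, i) * A(i, nxt); s += p[i]; }
    }
    if (s <= 0.0) stop("state-path sampling degenerated: zero total mass");
    double u = unif_rand() * s, acc = 0.0;
    int drawn = N - 1;
    for (int i = 0; i < N; ++i) {
      acc += p[i];
      if (u <= acc) { drawn = i; break; }
    }
    path[t] = drawn + 1;
  }
  return path;
}
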