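#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one chain.
//
// log_b: T x K matrix of (expected) log emission densities.
// log_pi: length-K log initial weights; log_A: K x K log transition weights.
// The weights may be sub-normalized (variational geometric-mean parameters);
// scaling absorbs the deficit and loglik returns log of the total path weight.
//
// Returns gamma (T x K, rows sum to 1), xi ((T-1) x K*K, row t holds the
// joint of (z_t, z_{t+1}) flattened column-major as K x K, sums to 1), and
// loglik.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix log_b, NumericVector log_pi, NumericMatrix log_A) {
  const int T = log_b.nrow(), K = log_b.ncol();
  NumericMatrix b(T, K);
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double mx = log_b(t, 0);
    for (int k = 1; k < K; ++k) if (log_b(t, k) > mx) mx = log_b(t, k);
    if (!R_finite(mx)) stop("non-finite emission log-density at timepoint %d", t + 1);
    shift[t] = mx;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(log_b(t, k) - mx);
  }
  NumericMatrix A(K, K);
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = std::exp(log_pi[k]);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) A(j, k) = std::exp(log_A(j, k));

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); s += alpha(0, k); }
  if (s <= 0) stop("forward recursion underflow at timepoint 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= b(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) stop("forward recursion underflow at timepoint %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double v = 0.0;
      for (int k = 0; k < K; ++k) v += A(j, k) * b(t + 1, k) * beta(t + 1, k);
      beta(t, j) = v / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(std::max(T - 1, 0), K * K);
  for (int t = 0; t + 1 < T; ++t) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j) {
        double v = alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k) / c[t + 1];
        xi(t, j + K * k) = v;
        tot += v;
      }
    for (int q = 0; q < K * K; ++q) xi(t, q) /= tot;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + shift[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Log-space Viterbi decoding; ties break toward the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix log_b, NumericVector log_pi,
                          NumericMatrix log_A) {
  const int T = log_b.nrow(), K = log_b.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = log_pi[k] + log_b(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + log_A(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + log_A(j, k);
        if (v > best) { best = v; arg = j; }  // strict: first (lowest) index wins ties
      }
      delta(t, k) = best + log_b(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return path;
}
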