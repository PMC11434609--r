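#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for one segment.
//
// Inputs are log quantities: logdens (T x K) per-frame log emission terms,
// logpi (K) initial log weights, logA (K x K) transition log weights. The
// weights need not normalize (variational expected parameters do not); the
// returned logZ is log of the sum over all paths of the products of the
// exponentiated inputs, and gamma / xi are the corresponding posterior
// marginals. Scaling constants keep everything in linear range.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logdens, NumericVector logpi, NumericMatrix logA) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix dens(T, K);
  std::vector<double> shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) if (logdens(t, k) > m) m = logdens(t, k);
    if (!std::isfinite(m)) stop("non-finite emission log-density");
    shift[t] = m;
    for (int k = 0; k < K; ++k) dens(t, k) = std::exp(logdens(t, k) - m);
  }
  std::vector<double> pi(K);
  NumericMatrix A(K, K);
  for (int j = 0; j < K; ++j) {
    pi[j] = std::exp(logpi[j]);
    for (int k = 0; k < K; ++k) A(j, k) = std::exp(logA(j, k));
  }

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  std::vector<double> norm(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * dens(0, k); s += alpha(0, k); }
  if (s <= 0) stop("forward pass underflow at frame 1");
  norm[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= dens(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) stop("forward pass underflow");
    norm[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * dens(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / norm[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    double tot = 0.0;
    NumericMatrix xt(K, K);
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        double v = alpha(t, j) * A(j, k) * dens(t + 1, k) * beta(t + 1, k);
        xt(j, k) = v;
        tot += v;
      }
    }
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += xt(j, k) / tot;
  }

  double logZ = 0.0;
  for (int t = 0; t < T; ++t) logZ += std::log(norm[t]) + shift[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["logZ"] = logZ);
}

// Exact most-probable path (max-product in log space) for one segment.
// Returns 1-based state indices. Ties resolve to the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
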