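#include <Rcpp.h>
using namespace Rcpp;

// log-sum-exp over a small fixed-size buffer
static inline double lse(const double *x, int n) {
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward-backward for a K-state chain with (optionally time-varying)
// transitions. logB is T x K emission log-likelihoods (rows of zeros encode
// missing observations); logA is a (T-1) x K x K array flattened column-major
// (logA[t + (T-1)*(i + K*j)] = log P(state j at t+1 | state i at t)).
// Returns loglik, gamma (T x K posteriors) and xi ((T-1) x K x K pairwise
// posteriors), all on the probability scale.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericVector logPi,
                          NumericVector logA) {
  const int T = logB.nrow(), K = logB.ncol();
  if (T < 2) stop("need at least 2 time points");
  const int TA = T - 1;
  NumericMatrix la(T, K), lb(T, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = logPi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int i = 0; i < K; ++i)
        buf[i] = la(t - 1, i) + logA[(t - 1) + TA * (i + K * j)];
      la(t, j) = lse(buf.data(), K) + logB(t, j);
    }
  }
  for (int k = 0; k < K; ++k) buf[k] = la(T - 1, k);
  const double loglik = lse(buf.data(), K);

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      for (int j = 0; j < K; ++j)
        buf[j] = logA[t + TA * (i + K * j)] + logB(t + 1, j) + lb(t + 1, j);
      lb(t, i) = lse(buf.data(), K);
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += gamma(t, k);
    if (s > 0) for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericVector xi(TA * K * K);
  for (int t = 0; t < TA; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = std::exp(la(t, i) + logA[t + TA * (i + K * j)] +
                            logB(t + 1, j) + lb(t + 1, j) - loglik);
        xi[t + TA * (i + K * j)] = v;
        s += v;
      }
    if (s > 0)
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j) xi[t + TA * (i + K * j)] /= s;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Global (Viterbi) decoding; same conventions as hmm_forward_backward.
// Returns 1-based state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericVector logPi,
                          NumericVector logA) {
  const int T = logB.nrow(), K = logB.ncol();
  const int TA = T - 1;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logPi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logA[(t - 1) + TA * (i + K * j)];
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
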