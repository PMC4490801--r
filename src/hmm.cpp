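#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a discrete-emission HMM.
// E is T x L with E(t, l) = P(obs_t | state l); A is L x L row-stochastic;
// pi0 is the initial distribution over the L states. Returns log p(obs).
// A zero normalizer at any step means the observation sequence is
// impossible under the model: return -Inf.
// [[Rcpp::export]]
double fwd_loglik_cpp(const NumericMatrix& E, const NumericMatrix& A,
                      const NumericVector& pi0) {
  const int T = E.nrow(), L = E.ncol();
  std::vector<double> alpha(L), nxt(L);
  double loglik = 0.0;

  double c = 0.0;
  for (int l = 0; l < L; ++l) {
    alpha[l] = pi0[l] * E(0, l);
    c += alpha[l];
  }
  if (c <= 0.0) return R_NegInf;
  for (int l = 0; l < L; ++l) alpha[l] /= c;
  loglik += std::log(c);

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int j = 0; j < L; ++j) s += alpha[j] * A(j, l);
      nxt[l] = s * E(t, l);
      c += nxt[l];
    }
    if (c <= 0.0) return R_NegInf;
    for (int l = 0; l < L; ++l) alpha[l] = nxt[l] / c;
    loglik += std::log(c);
  }
  return loglik;
}

// Forward-filter backward-sample: exact blocked draw of the hidden path
// from p(z | obs, theta, A, pi0). Uses R's RNG so set.seed() applies.
// Returns a 1-based path of length T. Errors if the sequence is impossible.
// [[Rcpp::export]]
IntegerVector ffbs_cpp(const NumericMatrix& E, const NumericMatrix& A,
                       const NumericVector& pi0) {
  const int T = E.nrow(), L = E.ncol();
  NumericMatrix alpha(T, L);
  IntegerVector path(T);

  double c = 0.0;
  for (int l = 0; l < L; ++l) {
    alpha(0, l) = pi0[l] * E(0, l);
    c += alpha(0, l);
  }
  if (c <= 0.0) stop("observation sequence has zero probability under the model");
  for (int l = 0; l < L; ++l) alpha(0, l) /= c;

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int j = 0; j < L; ++j) s += alpha(t - 1, j) * A(j, l);
      alpha(t, l) = s * E(t, l);
      c += alpha(t, l);
    }
    if (c <= 0.0) stop("observation sequence has zero probability under the model");
    for (int l = 0; l < L; ++l) alpha(t, l) /= c;
  }

  // sample z_T ~ alpha_T, then z_t | z_{t+1} prop to alpha_t(l) A(l, z_{t+1})
  double u = unif_rand(), acc = 0.0;
  int pick = L - 1;
  for (int l = 0; l < L; ++l) {
    acc += alpha(T - 1, l);
    if (u <= acc) { pick = l; break; }
  }
  path[T - 1] = pick + 1;

  std::vector<double> w(L);
  for (int t = T - 2; t >= 0; --t) {
    const int znext = path[t + 1] - 1;
    double tot = 0.0;
    for (int l = 0; l < L; ++l) {
      w[l] = alpha(t, l) * A(l, znext);
      tot += w[l];
    }
    u = unif_rand() * tot;
    acc = 0.0;
    pick = L - 1;
    for (int l = 0; l < L; ++l) {
      acc += w[l];
      if (u <= acc) { pick = l; break; }
    }
    path[t] = pick + 1;
  }
  return path;
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index (strict improvement required to move off an earlier candidate).
// Returns a 1-based path of length T.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(const NumericMatrix& E, const NumericMatrix& A,
                          const NumericVector& pi0) {
  const int T = E.nrow(), L = E.ncol();
  NumericMatrix delta(T, L);
  IntegerMatrix psi(T, L);
  IntegerVector path(T);

  for (int l = 0; l < L; ++l)
    delta(0, l) = std::log(pi0[l]) + std::log(E(0, l));

  for (int t = 1; t < T; ++t) {
    for (int l = 0; l < L; ++l) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < L; ++j) {
        const double cand = delta(t - 1, j) + std::log(A(j, l));
        if (cand > best) { best = cand; arg = j; }
      }
      delta(t, l) = best + std::log(E(t, l));
      psi(t, l) = arg;
    }
  }

  double best = R_NegInf;
  int arg = 0;
  for (int l = 0; l < L; ++l)
    if (delta(T - 1, l) > best) { best = delta(T - 1, l); arg = l; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi(t + 1, path[t + 1] - 1) + 1;
  return path;
}
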