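#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Core Poisson / zero-inflated-Poisson HMM recursions.
//
// Observations are small non-negative integers (seconds active per
// minute, 0-60), so per-state emission probabilities are tabulated once
// per EM iteration over the observed support and looked up per bin.  The
// forward-backward pass uses per-step scaling with a per-value shift of
// the emission probabilities, so bins that are very unlikely under every
// state (e.g. a 60 s/min bin under near-zero rates) stay finite.  Inner
// loops run over contiguous row-major buffers.

// Row-major (maxv+1) x K tables: shifted emission likelihoods and the
// per-value shift (max log emission over states).
struct EmissionTable {
  std::vector<double> b;      // exp(logB - shift), row-major by value
  std::vector<double> shift;  // per value
  int K;
  const double* row(int x) const { return &b[(size_t)x * K]; }
};

static EmissionTable make_emission_table(int maxv,
                                         const std::vector<double>& lambda,
                                         const std::vector<double>& w) {
  const int K = (int)lambda.size();
  const bool zip = !w.empty();
  EmissionTable tab;
  tab.K = K;
  tab.b.resize((size_t)(maxv + 1) * K);
  tab.shift.resize(maxv + 1);
  std::vector<double> logB(K);
  for (int x = 0; x <= maxv; ++x) {
    double m = -DBL_MAX;
    for (int k = 0; k < K; ++k) {
      double lp = R::dpois(x, lambda[k], 1);
      if (zip)
        lp = (x == 0) ? std::log(w[k] + (1.0 - w[k]) * std::exp(lp))
                      : std::log1p(-w[k]) + lp;
      logB[k] = lp;
      if (lp > m) m = lp;
    }
    tab.shift[x] = m;
    for (int k = 0; k < K; ++k)
      tab.b[(size_t)x * K + k] = std::exp(logB[k] - m);
  }
  return tab;
}

// Sufficient statistics accumulated over one sequence.
struct SuffStats {
  double loglik = 0.0;
  std::vector<double> gamma0;    // posterior of the first bin
  std::vector<double> xi;        // K x K summed two-slice posteriors
  std::vector<double> sum_g;     // per-state posterior mass
  std::vector<double> sum_gx;    // per-state posterior-weighted counts
  std::vector<double> sum_g0;    // per-state posterior mass at x == 0
};

// Scaled forward-backward; gamma_out (optional) receives T x K
// posteriors (row-major).  Returns log-likelihood; stats (optional)
// accumulates EM sufficient statistics.
static double forward_backward(const int* obs, int T,
                               const std::vector<double>& pi,
                               const std::vector<double>& A,
                               const EmissionTable& tab,
                               SuffStats* stats,
                               double* gamma_out) {
  const int K = (int)pi.size();
  std::vector<double> alpha((size_t)T * K), cvec(T);
  double loglik = 0.0;

  {  // forward
    const double* b0 = tab.row(obs[0]);
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = pi[k] * b0[k];
      c0 += alpha[k];
    }
    if (c0 <= 0.0) c0 = DBL_MIN;
    for (int k = 0; k < K; ++k) alpha[k] /= c0;
    cvec[0] = c0;
    loglik += std::log(c0) + tab.shift[obs[0]];
  }
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[(size_t)(t - 1) * K];
    double* an = &alpha[(size_t)t * K];
    const double* bt = tab.row(obs[t]);
    for (int j = 0; j < K; ++j) an[j] = 0.0;
    for (int i = 0; i < K; ++i) {
      const double ai = ap[i];
      const double* Ai = &A[(size_t)i * K];
      for (int j = 0; j < K; ++j) an[j] += ai * Ai[j];
    }
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      an[j] *= bt[j];
      ct += an[j];
    }
    if (ct <= 0.0) ct = DBL_MIN;
    for (int j = 0; j < K; ++j) an[j] /= ct;
    cvec[t] = ct;
    loglik += std::log(ct) + tab.shift[obs[t]];
  }

  if (!stats && !gamma_out) return loglik;

  // backward, posteriors and two-slice statistics
  std::vector<double> beta(K, 1.0), beta_prev(K), gamma(K);
  auto emit_gamma = [&](int t) {
    double gsum = 0.0;
    const double* at = &alpha[(size_t)t * K];
    for (int k = 0; k < K; ++k) {
      gamma[k] = at[k] * beta[k];
      gsum += gamma[k];
    }
    if (gsum > 0.0)
      for (int k = 0; k < K; ++k) gamma[k] /= gsum;
    if (gamma_out)
      for (int k = 0; k < K; ++k) gamma_out[(size_t)t * K + k] = gamma[k];
    if (stats) {
      const int x = obs[t];
      for (int k = 0; k < K; ++k) {
        stats->sum_g[k] += gamma[k];
        stats->sum_gx[k] += gamma[k] * x;
        if (x == 0) stats->sum_g0[k] += gamma[k];
      }
      if (t == 0)
        for (int k = 0; k < K; ++k) stats->gamma0[k] += gamma[k];
    }
  };

  emit_gamma(T - 1);
  for (int t = T - 2; t >= 0; --t) {
    beta_prev.swap(beta);  // beta_prev now holds beta_{t+1}
    const double* bt1 = tab.row(obs[t + 1]);
    const double inv_c = 1.0 / cvec[t + 1];
    std::vector<double> bb(K);
    for (int j = 0; j < K; ++j) bb[j] = bt1[j] * beta_prev[j] * inv_c;
    const double* at = &alpha[(size_t)t * K];
    for (int i = 0; i < K; ++i) {
      const double* Ai = &A[(size_t)i * K];
      double s = 0.0;
      if (stats) {
        double* xi = &stats->xi[(size_t)i * K];
        const double ai = at[i];
        for (int j = 0; j < K; ++j) {
          const double term = Ai[j] * bb[j];
          s += term;
          xi[j] += ai * term;
        }
      } else {
        for (int j = 0; j < K; ++j) s += Ai[j] * bb[j];
      }
      beta[i] = s;
    }
    emit_gamma(t);
  }
  if (stats) stats->loglik += loglik;
  return loglik;
}

static std::vector<double> as_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

// row-major copy of an R (column-major) K x K matrix
static std::vector<double> as_rowmajor(const NumericMatrix& A) {
  const int K = A.nrow();
  std::vector<double> out((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) out[(size_t)i * K + j] = A(i, j);
  return out;
}

static int max_obs(const List& obs_list) {
  int maxv = 0;
  for (int s = 0; s < obs_list.size(); ++s) {
    IntegerVector obs = obs_list[s];
    for (int t = 0; t < obs.size(); ++t)
      if (obs[t] > maxv) maxv = obs[t];
  }
  return maxv;
}

// [[Rcpp::export(name = ".cpp_hmm_loglik")]]
double cpp_hmm_loglik(List obs_list, NumericVector pi, NumericMatrix A,
                      NumericVector lambda, NumericVector w) {
  EmissionTable tab = make_emission_table(max_obs(obs_list),
                                          as_vec(lambda), as_vec(w));
  std::vector<double> piv = as_vec(pi), Av = as_rowmajor(A);
  double ll = 0.0;
  for (int s = 0; s < obs_list.size(); ++s) {
    IntegerVector obs = obs_list[s];
    ll += forward_backward(obs.begin(), obs.size(), piv, Av, tab,
                           nullptr, nullptr);
  }
  return ll;
}

// [[Rcpp::export(name = ".cpp_hmm_posteriors")]]
NumericMatrix cpp_hmm_posteriors(IntegerVector obs, NumericVector pi,
                                 NumericMatrix A, NumericVector lambda,
                                 NumericVector w) {
  const int T = obs.size(), K = pi.size();
  int maxv = 0;
  for (int t = 0; t < T; ++t) if (obs[t] > maxv) maxv = obs[t];
  EmissionTable tab = make_emission_table(maxv, as_vec(lambda),
                                          as_vec(w));
  std::vector<double> gamma((size_t)T * K);
  forward_backward(obs.begin(), T, as_vec(pi), as_rowmajor(A), tab,
                   nullptr, gamma.data());
  NumericMatrix out(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) out(t, k) = gamma[(size_t)t * K + k];
  return out;
}

// [[Rcpp::export(name = ".cpp_hmm_viterbi")]]
IntegerVector cpp_hmm_viterbi(IntegerVector obs, NumericVector pi,
                              NumericMatrix A, NumericVector lambda,
                              NumericVector w) {
  const int T = obs.size();
  const int K = pi.size();
  int maxv = 0;
  for (int t = 0; t < T; ++t) if (obs[t] > maxv) maxv = obs[t];
  const bool zip = w.size() == K;
  // log-space emission table
  std::vector<double> logB((size_t)(maxv + 1) * K);
  for (int x = 0; x <= maxv; ++x)
    for (int k = 0; k < K; ++k) {
      double lp = R::dpois(x, lambda[k], 1);
      if (zip)
        lp = (x == 0) ? std::log(w[k] + (1.0 - w[k]) * std::exp(lp))
                      : std::log1p(-w[k]) + lp;
      logB[(size_t)x * K + k] = lp;
    }
  std::vector<double> logA((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      logA[(size_t)i * K + j] = A(i, j) > 0.0 ? std::log(A(i, j))
                                              : -DBL_MAX;
  std::vector<double> delta((size_t)T * K);
  std::vector<int> psi((size_t)T * K);
  for (int k = 0; k < K; ++k)
    delta[k] = (pi[k] > 0.0 ? std::log(pi[k]) : -DBL_MAX) +
      logB[(size_t)obs[0] * K + k];
  for (int t = 1; t < T; ++t) {
    const double* dp = &delta[(size_t)(t - 1) * K];
    double* dn = &delta[(size_t)t * K];
    const double* bx = &logB[(size_t)obs[t] * K];
    for (int j = 0; j < K; ++j) {
      double best = -DBL_MAX;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = dp[i] + logA[(size_t)i * K + j];
        if (v > best) { best = v; arg = i; }  // ">" keeps lowest index
      }
      dn[j] = best + bx[j];
      psi[(size_t)t * K + j] = arg;
    }
  }
  IntegerVector path(T);
  const double* dl = &delta[(size_t)(T - 1) * K];
  double best = -DBL_MAX;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (dl[k] > best) { best = dl[k]; arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + path[t + 1]];
  return path;  // 0-based
}

// Baum-Welch EM over one or more sequences (sufficient statistics
// pooled, no transitions across sequence boundaries).  Stops when the
// log-likelihood gain drops below tol.  The returned log-likelihood is
// evaluated at the returned parameters.
// [[Rcpp::export(name = ".cpp_hmm_em")]]
List cpp_hmm_em(List obs_list, NumericVector pi0, NumericMatrix A0,
                NumericVector lambda0, NumericVector w0, bool use_zip,
                double tol, int max_iter, double lambda_floor) {
  const int K = pi0.size();
  const int S = obs_list.size();
  std::vector<double> pi = as_vec(pi0), lambda = as_vec(lambda0);
  std::vector<double> A = as_rowmajor(A0);
  std::vector<double> w = use_zip ? as_vec(w0) : std::vector<double>();
  const int maxv = max_obs(obs_list);

  // copy sequences once
  std::vector<std::vector<int>> seqs(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector obs = obs_list[s];
    seqs[s].assign(obs.begin(), obs.end());
  }

  std::vector<double> trail;
  trail.reserve(max_iter);
  double prev = -DBL_MAX;
  bool converged = false;
  LogicalVector collapsed(K);

  for (int it = 0; it < max_iter; ++it) {
    EmissionTable tab = make_emission_table(maxv, lambda, w);
    SuffStats st;
    st.gamma0.assign(K, 0.0);
    st.xi.assign((size_t)K * K, 0.0);
    st.sum_g.assign(K, 0.0);
    st.sum_gx.assign(K, 0.0);
    st.sum_g0.assign(K, 0.0);
    for (int s = 0; s < S; ++s)
      forward_backward(seqs[s].data(), (int)seqs[s].size(), pi, A, tab,
                       &st, nullptr);
    const double ll = st.loglik;
    trail.push_back(ll);
    if (it > 0 && ll - prev < tol) { converged = true; break; }
    prev = ll;
    if (it == max_iter - 1) break;  // params must match reported loglik

    // M-step
    for (int k = 0; k < K; ++k) pi[k] = st.gamma0[k] / S;
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += st.xi[(size_t)i * K + j];
      if (rs > 0.0)
        for (int j = 0; j < K; ++j) A[(size_t)i * K + j] =
          st.xi[(size_t)i * K + j] / rs;
      // rs == 0: state unvisited before the final bin; keep previous row
    }
    for (int k = 0; k < K; ++k) {
      if (st.sum_g[k] < 1e-8) {
        lambda[k] = lambda_floor;
        collapsed[k] = true;
        continue;
      }
      double sum_gz = 0.0;
      if (use_zip) {
        // posterior probability that an x == 0 bin came from the spike
        const double pz = std::exp(-lambda[k]);
        const double z = w[k] / (w[k] + (1.0 - w[k]) * pz);
        sum_gz = st.sum_g0[k] * z;
      }
      const double denom = use_zip ? (st.sum_g[k] - sum_gz) : st.sum_g[k];
      double lam = denom > 0.0 ? st.sum_gx[k] / denom : lambda_floor;
      lambda[k] = std::max(lam, lambda_floor);
      if (use_zip) {
        double wk = sum_gz / st.sum_g[k];
        if (wk < 0.0) wk = 0.0;
        if (wk > 1.0 - 1e-9) wk = 1.0 - 1e-9;
        w[k] = wk;
      }
    }
  }

  NumericMatrix Aout(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Aout(i, j) = A[(size_t)i * K + j];
  return List::create(
    _["initial"] = NumericVector(pi.begin(), pi.end()),
    _["transitions"] = Aout,
    _["lambdas"] = NumericVector(lambda.begin(), lambda.end()),
    _["zeroWeights"] = NumericVector(w.begin(), w.end()),
    _["logLik"] = trail.back(),
    _["trail"] = NumericVector(trail.begin(), trail.end()),
    _["nIter"] = (int)trail.size(), _["converged"] = converged,
    _["collapsed"] = collapsed);
}
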