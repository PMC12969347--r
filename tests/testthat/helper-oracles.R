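# Independent brute-force oracles for small HMM instances: exhaustive
# enumeration over all K^T hidden paths, computed directly from the joint
# probability, with no shared code with the package's recursions.

enum_paths <- function(K, T) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(K)), T)))
}

path_logprob <- function(path, pi, A, lam, obs, w = NULL) {
  lp <- log(pi[path[1]])
  if (length(path) > 1)
    for (t in 2:length(path)) lp <- lp + log(A[path[t - 1], path[t]])
  for (t in seq_along(path)) {
    em <- dpois(obs[t], lam[path[t]])
    if (!is.null(w))
      em <- w[path[t]] * (obs[t] == 0) + (1 - w[path[t]]) * em
    lp <- lp + log(em)
  }
  lp
}

brute_loglik <- function(pi, A, lam, obs, w = NULL) {
  paths <- enum_paths(length(pi), length(obs))
  lps <- apply(paths, 1, path_logprob, pi = pi, A = A, lam = lam,
               obs = obs, w = w)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

brute_posteriors <- function(pi, A, lam, obs, w = NULL) {
  K <- length(pi)
  T <- length(obs)
  paths <- enum_paths(K, T)
  p <- exp(apply(paths, 1, path_logprob, pi = pi, A = A, lam = lam,
                 obs = obs, w = w))
  gamma <- matrix(0, T, K)
  for (t in seq_len(T))
    for (k in seq_len(K))
      gamma[t, k] <- sum(p[paths[, t] == k])
  gamma / rowSums(gamma)
}

# Most probable path; returns NULL when the top two paths are within
# `gap` in log-probability (tie handling differs between oracle and
# dynamic program, so such instances are skipped by callers).
brute_viterbi <- function(pi, A, lam, obs, w = NULL, gap = 1e-9) {
  paths <- enum_paths(length(pi), length(obs))
  lps <- apply(paths, 1, path_logprob, pi = pi, A = A, lam = lam,
               obs = obs, w = w)
  ord <- order(lps, decreasing = TRUE)
  if (length(lps) > 1 && lps[ord[1]] - lps[ord[2]] < gap) return(NULL)
  as.integer(paths[ord[1], ])
}

# Random valid HMM parameters for property tests.
rand_hmm <- function(K, seed) {
  set.seed(seed)
  pi <- rgamma(K, 1) + 0.05
  pi <- pi / sum(pi)
  A <- matrix(rgamma(K * K, 1) + 0.05, K, K)
  A <- A / rowSums(A)
  lam <- sort(runif(K, 0.1, 12))
  HMMParams(pi, A, lam)
}

# Textbook step-up FDR adjustment, coded independently.
reference_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[ro]
}

# Exact two-sided signed-rank p by full sign-flip enumeration (no ties).
reference_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- enum_paths(2, n) - 1  # all 2^n sign assignments
  v_null <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(v_null - mu) >= abs(v_obs - mu) - 1e-12)
}
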