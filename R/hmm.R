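#' @include AllClasses.R utils.R
#' @useDynLib sleepHMM, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Rate floor: keeps zero-rate states non-degenerate.  Far below the lowest
# rate seen in real data (deep sleep sits near 0.02 s/min).
LAMBDA_FLOOR <- 1e-3

#' Construct HMM parameters
#'
#' @param initial length-K initial state distribution.
#' @param transitions K x K row-stochastic transition matrix.
#' @param lambdas per-state Poisson means (s/min); floored at 1e-3.
#' @param zeroWeights optional per-state zero-inflation weights in [0, 1);
#'   omit (length 0) for a plain Poisson model.
#' @return An [HMMParams-class].
#' @export
HMMParams <- function(initial, transitions, lambdas,
                      zeroWeights = numeric(0)) {
  K <- length(lambdas)
  new("HMMParams", K = as.integer(K), initial = as.numeric(initial),
      transitions = matrix(as.numeric(transitions), K, K),
      lambdas = pmax(as.numeric(lambdas), LAMBDA_FLOOR),
      zeroWeights = as.numeric(zeroWeights))
}

# Coerce traces / integer vectors / lists thereof to a list of
# non-negative integer observation vectors.
.obs_list <- function(x) {
  one <- function(el) {
    if (is(el, "ActivityTrace")) return(el@values)
    v <- as.integer(el)
    .stop_if(length(v) < 1L, "empty observation sequence")
    .stop_if(anyNA(v) || any(v < 0L),
             "observations must be non-negative integers")
    v
  }
  if (is.list(x) && !is(x, "ActivityTrace")) lapply(x, one) else list(one(x))
}

.zw <- function(params) {
  if (length(params@zeroWeights)) params@zeroWeights else numeric(0)
}

#' Poisson / zero-inflated Poisson emission log-probability
#'
#' \code{log P(x | lambda)} for a Poisson state, or, with a zero-weight
#' \code{w}, \code{log(w \[x = 0\] + (1 - w) Pois(x; lambda))}.
#'
#' @param x non-negative integer count(s) (seconds active per minute).
#' @param lambda Poisson mean.
#' @param w optional zero-inflation weight in [0, 1).
#' @return Log-probability, vectorized over \code{x}.
#' @export
emissionLogPmf <- function(x, lambda, w = NULL) {
  .stop_if(any(x < 0) || any(x != round(x)),
           "x must be non-negative integers")
  .stop_if(lambda <= 0, "lambda must be positive")
  lp <- stats::dpois(x, lambda, log = TRUE)
  if (is.null(w)) return(lp)
  .stop_if(w < 0 || w >= 1, "w must be in [0, 1)")
  ifelse(x == 0, log(w + (1 - w) * exp(lp)), log1p(-w) + lp)
}

#' Marginal log-likelihood of observation sequences under an HMM
#'
#' Exact marginal log-likelihood via the scaled forward recursion, summed
#' over sequences (no transitions across sequence boundaries).
#'
#' @param params an [HMMParams-class].
#' @param traces an [ActivityTrace-class], integer vector, or list of
#'   either.
#' @return Log-likelihood (finite for any valid input).
#' @export
hmmLogLik <- function(params, traces) {
  stopifnot(is(params, "HMMParams"))
  obs <- .obs_list(traces)
  .cpp_hmm_loglik(obs, params@initial, params@transitions,
                  params@lambdas, .zw(params))
}

#' Posterior state probabilities (forward-backward smoothing)
#'
#' @param params an [HMMParams-class].
#' @param trace a single [ActivityTrace-class] or integer vector.
#' @return T x K matrix of \code{P(state_t = k | x_1..T)}; rows sum to 1.
#' @export
statePosteriors <- function(params, trace) {
  stopifnot(is(params, "HMMParams"))
  obs <- .obs_list(trace)
  .stop_if(length(obs) != 1L, "statePosteriors takes a single sequence")
  .cpp_hmm_posteriors(obs[[1L]], params@initial, params@transitions,
                      params@lambdas, .zw(params))
}

#' Viterbi decoding: jointly most probable state path
#'
#' Ties are broken toward the lower state index, making decoded paths
#' deterministic.
#'
#' @param params an [HMMParams-class].
#' @param trace a single [ActivityTrace-class] or integer vector.
#' @return Integer vector of 1-based state indices.
#' @export
viterbiPath <- function(params, trace) {
  stopifnot(is(params, "HMMParams"))
  obs <- .obs_list(trace)
  .stop_if(length(obs) != 1L, "viterbiPath takes a single sequence")
  .cpp_hmm_viterbi(obs[[1L]], params@initial, params@transitions,
                   params@lambdas, .zw(params)) + 1L
}

#' Decode a trace: Viterbi path plus posteriors
#'
#' @param params an [HMMParams-class].
#' @param trace a single [ActivityTrace-class] or integer vector.
#' @param labeling optional [StateLabeling-class] to attach.
#' @return A [StateSequence-class].
#' @export
decodeStates <- function(params, trace, labeling = NULL) {
  post <- statePosteriors(params, trace)
  new("StateSequence", states = viterbiPath(params, trace),
      posteriors = post,
      labeling = if (is.null(labeling)) character(0)
                 else stateLabels(labeling))
}

# Restart initialization (EM is only locally convergent):
#  - lambdas: K interior quantiles of the pooled observations, pushed off
#    zero, with multiplicative lognormal jitter;
#  - transitions: near-diagonal (self-transition 0.8, rest uniform) with
#    gamma (Dirichlet-like) jitter;
#  - initial: uniform.
.init_params <- function(obs, K, seed, emission) {
  withSeed(seed, {
    pooled <- unlist(obs)
    q <- as.numeric(stats::quantile(pooled, probs = (seq_len(K) - 0.5) / K))
    lam <- pmax(q, 0.05) * exp(stats::rnorm(K, 0, 0.3))
    lam <- pmax(sort(lam), LAMBDA_FLOOR)
    A <- matrix(0.2 / max(K - 1, 1), K, K)
    diag(A) <- if (K > 1) 0.8 else 1
    A <- A * matrix(stats::rgamma(K * K, shape = 30, rate = 30), K, K)
    A <- A / rowSums(A)
    zw <- if (emission == "zip") stats::runif(K, 0, 0.2) else numeric(0)
    HMMParams(rep(1 / K, K), A, lam, zw)
  })
}

#' Fit an HMM by Baum-Welch EM
#'
#' Multi-sequence expectation-maximization for Poisson or zero-inflated
#' Poisson emissions.  Sufficient statistics are pooled across sequences
#' with no transitions across sequence boundaries.  The log-likelihood is
#' non-decreasing over iterations; fitting stops when the gain drops below
#' \code{tol} or after \code{maxIter} iterations.
#'
#' @param traces an [ActivityTrace-class], integer vector, [Cohort-class],
#'   or list of traces/vectors.
#' @param K number of hidden states.
#' @param initSeed RNG seed for the random initialization.
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param maxIter maximum EM iterations (default 500).
#' @param emission \code{"poisson"} or \code{"zip"}.
#' @param init optional explicit [HMMParams-class] initialization
#'   (overrides the seeded random initialization).
#' @return A [FitResult-class].
#' @export
fitEM <- function(traces, K, initSeed = 1L, tol = 1e-4, maxIter = 500L,
                  emission = c("poisson", "zip"), init = NULL) {
  emission <- match.arg(emission)
  if (is(traces, "Cohort")) traces <- cohortTraces(traces)
  obs <- .obs_list(traces)
  K <- as.integer(K)
  .stop_if(K < 1L, "K must be >= 1")
  .stop_if(sum(lengths(obs)) < K, "need at least K observations in total")
  if (is.null(init)) init <- .init_params(obs, K, initSeed, emission)
  use_zip <- emission == "zip"
  zw0 <- if (use_zip) {
    if (length(init@zeroWeights)) init@zeroWeights else rep(0.1, K)
  } else numeric(0)
  res <- .cpp_hmm_em(obs, init@initial, init@transitions, init@lambdas,
                     zw0, use_zip, tol, as.integer(maxIter), LAMBDA_FLOOR)
  if (any(res$collapsed))
    warning("state(s) collapsed during EM; rate floored at ", LAMBDA_FLOOR)
  new("FitResult",
      params = HMMParams(res$initial, res$transitions, res$lambdas,
                         res$zeroWeights),
      logLik = res$logLik, nIter = as.integer(res$nIter),
      converged = res$converged, seed = as.integer(initSeed),
      trail = res$trail, collapsed = res$collapsed)
}

#' Sample an observation sequence from an HMM
#'
#' Draws a hidden path from the initial distribution and transition matrix
#' and per-bin observations from the state emission distribution.
#' Observations above 60 s/min (possible under an unbounded Poisson, not
#' in real data) are clipped, and clip events counted.
#'
#' @param params an [HMMParams-class].
#' @param T sequence length in 1-min bins.
#' @param seed RNG seed (reproducible).
#' @param fishId id for the generated trace.
#' @param startClock start time for the generated trace.
#' @return List with \code{trace} ([ActivityTrace-class]), \code{path}
#'   (hidden state indices) and \code{nClipped}.
#' @export
sampleHMM <- function(params, T, seed = 1L, fishId = "sim",
                      startClock = .default_start()) {
  stopifnot(is(params, "HMMParams"))
  .stop_if(T < 1, "T must be >= 1")
  K <- params@K
  withSeed(seed, {
    path <- integer(T)
    path[1L] <- sample.int(K, 1L, prob = params@initial)
    A <- params@transitions
    for (t in seq_len(T - 1L))
      path[t + 1L] <- sample.int(K, 1L, prob = A[path[t], ])
    x <- stats::rpois(T, params@lambdas[path])
    if (length(params@zeroWeights)) {
      zero <- stats::runif(T) < params@zeroWeights[path]
      x[zero] <- 0L
    }
    nClipped <- sum(x > 60L)
    x <- pmin(x, 60L)
    list(trace = ActivityTrace(fishId, x, startClock), path = path,
         nClipped = nClipped)
  })
}

#' Stationary distribution of a transition matrix
#'
#' The long-run state occupancy: the dominant (unit-eigenvalue) left
#' eigenvector of the row-stochastic transition matrix, normalized to sum
#' to 1.  If the unit eigenvalue is not simple (reducible or periodic
#' chain), falls back to the empirical state frequencies of a supplied
#' decoded path, or errors if none is given.
#'
#' @param A row-stochastic matrix (or an [HMMParams-class]).
#' @param fallbackStates optional decoded state indices used when the
#'   chain has no unique stationary distribution.
#' @return Probability vector of length K.
#' @export
stationaryDistribution <- function(A, fallbackStates = NULL) {
  if (is(A, "HMMParams")) A <- A@transitions
  .stop_if(!is.matrix(A) || nrow(A) != ncol(A),
           "A must be a square matrix")
  .stop_if(any(A < -1e-12) || any(abs(rowSums(A) - 1) > 1e-8),
           "A must be row-stochastic")
  K <- nrow(A)
  if (K == 1L) return(1)
  e <- eigen(t(A))
  unit <- which(abs(e$values - 1) < 1e-8)
  if (length(unit) != 1L) {
    if (!is.null(fallbackStates)) {
      tab <- tabulate(fallbackStates, nbins = K)
      return(tab / sum(tab))
    }
    stop("unit eigenvalue is not simple; supply fallbackStates",
         call. = FALSE)
  }
  v <- Re(e$vectors[, unit])
  v <- v / sum(v)
  .stop_if(any(v < -1e-8), "stationary distribution failed to converge")
  pmax(v, 0) / sum(pmax(v, 0))
}
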