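#' @include hmm.R
NULL

#' Best-of-n-restarts EM fit
#'
#' EM converges only locally, so each fit is repeated from
#' \code{nRestarts} random initializations and the fit with the maximum
#' log-likelihood is kept.  Restart seeds are derived deterministically
#' from \code{baseSeed}, so repeated calls are bit-identical.
#'
#' @param traces traces as accepted by [fitEM()].
#' @param K number of hidden states.
#' @param nRestarts number of random restarts (the reference protocol for
#'   real recordings is 1000; well-separated synthetic data needs far
#'   fewer).
#' @param baseSeed seed from which restart seeds are derived.
#' @param ... passed to [fitEM()] (tol, maxIter, emission).
#' @return The winning [FitResult-class]; its \code{seed} slot records the
#'   winning restart's seed.
#' @export
fitMultistart <- function(traces, K, nRestarts = 20L, baseSeed = 1L, ...) {
  .stop_if(nRestarts < 1L, "nRestarts must be >= 1")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- fitEM(traces, K, initSeed = deriveSeed(baseSeed, r), ...)
    if (is.null(best) || fit@logLik > best@logLik) best <- fit
  }
  best
}

#' Bayesian Information Criterion of a fit
#'
#' \code{BIC = p log(n) - 2 logLik} with free-parameter count
#' \code{p = (K - 1) + K (K - 1) + K = K^2 + K - 1} for Poisson emissions
#' (initial distribution, transition rows, rates) and
#' \code{p = K^2 + 2 K - 1} for zero-inflated Poisson (plus K
#' zero-weights).  Lower is better.
#'
#' @param fit a [FitResult-class].
#' @param nObs total number of observations the fit used.
#' @return BIC value.
#' @export
bic <- function(fit, nObs) {
  stopifnot(is(fit, "FitResult"))
  .stop_if(nObs < 1, "nObs must be >= 1")
  K <- fit@params@K
  p <- K^2 + K - 1 + if (length(fit@params@zeroWeights)) K else 0
  p * log(nObs) - 2 * fit@logLik
}

#' Select the optimal number of hidden states by BIC
#'
#' Fits multi-restart HMMs for each K in \code{kRange} and selects the
#' BIC-minimizing state count; BIC ties break toward smaller K
#' (parsimony).  When the two lowest-rate states of the winning fit are
#' nearly identical a state-similarity warning is attached.
#'
#' @param traces traces as accepted by [fitEM()].
#' @param kRange candidate state counts (default 2:6).
#' @param nRestarts restarts per K.
#' @param baseSeed seed; each K gets an independent derived seed stream.
#' @param ... passed to [fitEM()].
#' @return A [SelectionResult-class].
#' @export
optimalStateNumber <- function(traces, kRange = 2:6, nRestarts = 20L,
                               baseSeed = 1L, ...) {
  .stop_if(length(kRange) < 1L, "kRange must be non-empty")
  if (is(traces, "Cohort")) traces <- cohortTraces(traces)
  nObs <- sum(lengths(.obs_list(traces)))
  fits <- list()
  tab <- data.frame(K = integer(0), logLik = numeric(0), bic = numeric(0))
  for (i in seq_along(kRange)) {
    K <- kRange[i]
    fit <- fitMultistart(traces, K, nRestarts = nRestarts,
                         baseSeed = deriveSeed(baseSeed, 1000L + K), ...)
    fits[[as.character(K)]] <- fit
    tab <- rbind(tab, data.frame(K = K, logLik = fit@logLik,
                                 bic = bic(fit, nObs)))
  }
  sel <- tab$K[order(tab$bic, tab$K)][1L]
  best <- fits[[as.character(sel)]]
  lam <- sort(best@params@lambdas)
  occ <- tryCatch(stationaryDistribution(best@params@transitions),
                  error = function(e) NULL)
  if ((length(lam) > 1L && min(diff(lam)) < 0.05) ||
      (!is.null(occ) && min(occ) < 0.08))
    warning("selected fit has nearly identical state rates or a ",
            "near-empty state (possible over-segmentation)")
  new("SelectionResult", fits = fits, bicTable = tab,
      selectedK = as.integer(sel), nRestarts = as.integer(nRestarts))
}

#' Reference 4-state wild-type model
#'
#' The 4-state Poisson HMM used for surrogate-data experiments: state
#' rates are the group-level wild-type fitted means (0.02, 1.18, 4.07,
#' 7.49 s/min for S2, S1, W1, W2), and the transition matrix uses the
#' reported group-average off-diagonal probabilities where available
#' (S2->W1 0.03, S2->W2 0.01, S1->W1 0.07, S1->W2 0.07, W1->S1 0.09,
#' W1->S2 0.09, W2->S1 0.04, W2->S2 0.01); unreported off-diagonal
#' entries are set to a small equal value (0.05) and the diagonals absorb
#' the remainder, giving a strongly self-persistent chain.  This is an
#' approximation of any individual fish's fitted matrix.
#'
#' @return An [HMMParams-class] with states ordered S2, S1, W1, W2.
#' @export
wtReferenceParams <- function() {
  lam <- c(0.02, 1.18, 4.07, 7.49)
  A <- matrix(0, 4, 4,
              dimnames = list(c("S2", "S1", "W1", "W2"),
                              c("S2", "S1", "W1", "W2")))
  A["S2", c("S1", "W1", "W2")] <- c(0.05, 0.03, 0.01)
  A["S1", c("S2", "W1", "W2")] <- c(0.05, 0.07, 0.07)
  A["W1", c("S2", "S1", "W2")] <- c(0.09, 0.09, 0.05)
  A["W2", c("S2", "S1", "W1")] <- c(0.01, 0.04, 0.05)
  diag(A) <- 1 - rowSums(A)
  HMMParams(initial = stationaryDistribution(A), transitions = A,
            lambdas = lam)
}

#' Surrogate-data state-number recovery experiment
#'
#' Samples \code{nSequences} observation sequences of length \code{T}
#' from a known generator, reselects the state number for each by
#' multi-restart EM + BIC, and reports the fraction recovering the
#' generating K together with the full histogram of selected K*.
#'
#' @param gen generating [HMMParams-class].
#' @param nSequences number of surrogate sequences.
#' @param T sequence length in bins (2880 = 48 h).
#' @param kRange candidate state counts.
#' @param nRestarts restarts per K per sequence.
#' @param seed base seed.
#' @return List with \code{fraction} (recovery rate), \code{histogram}
#'   (table of selected K*), and \code{selected} (per-sequence K*).
#' @export
stateNumberRecoveryExperiment <- function(gen, nSequences = 50L, T = 2880L,
                                          kRange = 2:6, nRestarts = 20L,
                                          seed = 1L) {
  stopifnot(is(gen, "HMMParams"))
  selected <- integer(nSequences)
  for (s in seq_len(nSequences)) {
    sim <- sampleHMM(gen, T, seed = deriveSeed(seed, 2L * s))
    sel <- suppressWarnings(
      optimalStateNumber(sim$trace, kRange = kRange,
                         nRestarts = nRestarts,
                         baseSeed = deriveSeed(seed, 2L * s + 1L)))
    selected[s] <- sel@selectedK
  }
  list(fraction = mean(selected == gen@K),
       histogram = table(factor(selected, levels = sort(unique(
         c(kRange, gen@K))))),
       selected = selected)
}

# Align a fitted model's states to a generator's by ascending rate and
# return mean absolute deviations of rates and transition entries.
.alignment_error <- function(fit_params, gen) {
  pf <- order(fit_params@lambdas)
  pg <- order(gen@lambdas)
  lam_err <- mean(abs(fit_params@lambdas[pf] - gen@lambdas[pg]))
  A_err <- mean(abs(fit_params@transitions[pf, pf] -
                    gen@transitions[pg, pg]))
  c(lambda = lam_err, transition = A_err)
}

#' Data-length sufficiency experiment
#'
#' Samples surrogate sequences of increasing length from a known
#' generator, refits a K = gen K model to each, and summarizes
#' parameter-recovery error (mean absolute deviation of rate and
#' transition entries after aligning states by ascending rate).  Recovery
#' error shrinks as recordings lengthen; 48 h of 1-min bins is the
#' reference recording length.
#'
#' @param gen generating [HMMParams-class].
#' @param lengths sequence lengths in bins (default 600, 1440, 2880,
#'   4320 = 10, 24, 48, 72 h).
#' @param nReps replicate sequences per length.
#' @param nRestarts restarts per fit.
#' @param seed base seed.
#' @return data.frame with columns \code{length}, \code{lambdaMAD},
#'   \code{transitionMAD} (means over replicates).
#' @export
lengthSufficiencyExperiment <- function(gen,
                                        lengths = c(600L, 1440L, 2880L,
                                                    4320L),
                                        nReps = 20L, nRestarts = 5L,
                                        seed = 1L) {
  stopifnot(is(gen, "HMMParams"))
  .stop_if(any(lengths <= 0), "lengths must be positive")
  out <- lapply(seq_along(lengths), function(i) {
    errs <- vapply(seq_len(nReps), function(r) {
      s <- deriveSeed(seed, i * 10000L + r)
      sim <- sampleHMM(gen, lengths[i], seed = s)
      fit <- suppressWarnings(
        fitMultistart(sim$trace, gen@K, nRestarts = nRestarts,
                      baseSeed = deriveSeed(s, 1L)))
      .alignment_error(fit@params, gen)
    }, numeric(2))
    data.frame(length = lengths[i], lambdaMAD = mean(errs["lambda", ]),
               transitionMAD = mean(errs["transition", ]))
  })
  do.call(rbind, out)
}
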