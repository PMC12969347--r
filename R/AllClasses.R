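#' @import methods
NULL

setOldClass("POSIXct")

#' Raw (sub-minute) activity recording for one fish
#'
#' Holds a per-sample locomotor activity magnitude series (pixel-change
#' units or a binary active flag) sampled at \code{sampleRate} Hz, anchored
#' to clock time.  Raw series are binned to [ActivityTrace-class] objects
#' with [binActivity()].
#'
#' @slot fishId single identifier string.
#' @slot startClock POSIXct time of the first sample.
#' @slot sampleRate samples per second (>= 1).
#' @slot values non-negative activity magnitudes, one per sample.
#' @export
setClass("RawActivitySeries",
  representation(fishId = "character", startClock = "POSIXct",
                 sampleRate = "numeric", values = "numeric"))

setValidity("RawActivitySeries", function(object) {
  msg <- character()
  if (length(object@fishId) != 1L || !nzchar(object@fishId))
    msg <- c(msg, "fishId must be a single non-empty string")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@values) < 1L)
    msg <- c(msg, "values must contain at least one sample")
  if (anyNA(object@values) || any(object@values < 0))
    msg <- c(msg, "values must be non-negative and non-missing")
  if (length(msg)) msg else TRUE
})

#' One-minute binned activity trace for one fish
#'
#' The observation sequence of the hidden Markov analysis: integer seconds
#' of locomotor activity per minute (0-60), anchored to clock time.
#'
#' @slot fishId single identifier string.
#' @slot startClock POSIXct start time of the first bin.
#' @slot binWidth bin width in seconds; fixed at 60.
#' @slot values integer vector in [0, 60], one value per minute.
#' @export
setClass("ActivityTrace",
  representation(fishId = "character", startClock = "POSIXct",
                 binWidth = "numeric", values = "integer"))

setValidity("ActivityTrace", function(object) {
  msg <- character()
  if (length(object@fishId) != 1L || !nzchar(object@fishId))
    msg <- c(msg, "fishId must be a single non-empty string")
  if (!identical(as.numeric(object@binWidth), 60))
    msg <- c(msg, "binWidth must be 60 seconds")
  if (length(object@values) < 1L)
    msg <- c(msg, "trace must contain at least one bin")
  if (anyNA(object@values) ||
      any(object@values < 0L) || any(object@values > 60L))
    msg <- c(msg, "activity values must be integers in [0, 60]")
  if (length(msg)) msg else TRUE
})

#' Light schedule: labeled, contiguous lighting intervals
#'
#' Ordered, non-overlapping, contiguous intervals, each labeled with a
#' lighting condition.  Conditions \code{light} and \code{subjective_day}
#' map to period \code{day}; \code{dark} and \code{subjective_night} map to
#' \code{night}.  Intervals are half-open \code{[start, end)}.
#'
#' @slot intervals data.frame with POSIXct columns \code{start}, \code{end}
#'   and character column \code{condition}.
#' @export
setClass("LightSchedule", representation(intervals = "data.frame"))

.schedule_conditions <- c("light", "dark", "subjective_day",
                          "subjective_night")

setValidity("LightSchedule", function(object) {
  iv <- object@intervals
  msg <- character()
  if (!all(c("start", "end", "condition") %in% names(iv)))
    return("intervals needs columns start, end, condition")
  if (nrow(iv) < 1L) msg <- c(msg, "schedule must contain >= 1 interval")
  if (!all(iv$condition %in% .schedule_conditions))
    msg <- c(msg, paste("conditions must be one of:",
                        paste(.schedule_conditions, collapse = ", ")))
  if (nrow(iv) >= 1L && any(as.numeric(iv$end) <= as.numeric(iv$start)))
    msg <- c(msg, "each interval must satisfy start < end")
  if (nrow(iv) > 1L) {
    s <- as.numeric(iv$start); e <- as.numeric(iv$end)
    if (is.unsorted(s)) msg <- c(msg, "intervals must be ordered by start")
    else if (any(abs(e[-nrow(iv)] - s[-1L]) > 1e-6))
      msg <- c(msg, "intervals must be contiguous (end[i] == start[i+1])")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort of activity traces
#'
#' A labeled group of fish (e.g. one genotype or treatment arm) with one
#' [ActivityTrace-class] per fish and optional per-fish metadata.
#'
#' @slot label group label.
#' @slot traces list of [ActivityTrace-class] objects with unique fish ids.
#' @slot metadata data.frame of per-fish annotations (may have 0 columns).
#' @export
setClass("Cohort",
  representation(label = "character", traces = "list",
                 metadata = "data.frame"))

setValidity("Cohort", function(object) {
  msg <- character()
  if (length(object@traces) < 1L)
    msg <- c(msg, "cohort must contain at least one trace")
  if (!all(vapply(object@traces, is, logical(1), "ActivityTrace")))
    msg <- c(msg, "all traces must be ActivityTrace objects")
  else {
    ids <- vapply(object@traces, function(x) x@fishId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "fish ids must be unique within a cohort")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of a K-state Poisson (or zero-inflated Poisson) HMM
#'
#' @slot K number of hidden states.
#' @slot initial length-K initial state distribution.
#' @slot transitions K x K row-stochastic transition matrix.
#' @slot lambdas per-state Poisson mean activity (s/min), >= the rate floor.
#' @slot zeroWeights per-state zero-inflation weights in [0, 1); length 0
#'   for a plain Poisson model.
#' @export
setClass("HMMParams",
  representation(K = "integer", initial = "numeric",
                 transitions = "matrix", lambdas = "numeric",
                 zeroWeights = "numeric"))

setValidity("HMMParams", function(object) {
  msg <- character()
  K <- object@K
  if (length(K) != 1L || K < 1L) return("K must be a positive integer")
  if (length(object@initial) != K || abs(sum(object@initial) - 1) > 1e-9 ||
      any(object@initial < -1e-12))
    msg <- c(msg, "initial must be a length-K probability vector")
  A <- object@transitions
  if (!all(dim(A) == c(K, K)) || any(A < -1e-12) ||
      any(abs(rowSums(A) - 1) > 1e-9))
    msg <- c(msg, "transitions must be a K x K row-stochastic matrix")
  if (length(object@lambdas) != K || any(object@lambdas <= 0))
    msg <- c(msg, "lambdas must be K positive rates")
  zw <- object@zeroWeights
  if (length(zw) && (length(zw) != K || any(zw < 0) || any(zw >= 1)))
    msg <- c(msg, "zeroWeights must be length K with values in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Result of one EM fit
#'
#' @slot params fitted [HMMParams-class].
#' @slot logLik log-likelihood at the fitted parameters.
#' @slot nIter number of EM iterations run.
#' @slot converged whether the tolerance was reached before maxIter.
#' @slot seed the RNG seed that produced the initialization.
#' @slot trail per-iteration log-likelihood values (non-decreasing).
#' @slot collapsed logical per state: TRUE if the state lost all posterior
#'   mass and its rate was floored.
#' @export
setClass("FitResult",
  representation(params = "HMMParams", logLik = "numeric",
                 nIter = "integer", converged = "logical",
                 seed = "integer", trail = "numeric",
                 collapsed = "logical"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (length(object@trail) && length(object@trail) != object@nIter)
    msg <- c(msg, "trail length must equal nIter")
  if (length(object@trail) > 1L &&
      any(diff(object@trail) < -1e-8 * pmax(1, abs(object@trail[-1]))))
    msg <- c(msg, "log-likelihood trail must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Decoded state sequence with posteriors
#'
#' @slot states length-T vector of 1-based state indices (Viterbi path).
#' @slot posteriors T x K matrix of smoothing posteriors; rows sum to 1.
#' @slot labeling character vector mapping state index to semantic label
#'   (length 0 when unlabeled).
#' @export
setClass("StateSequence",
  representation(states = "integer", posteriors = "matrix",
                 labeling = "character"))

setValidity("StateSequence", function(object) {
  msg <- character()
  Tn <- length(object@states)
  K <- ncol(object@posteriors)
  if (nrow(object@posteriors) != Tn)
    msg <- c(msg, "posteriors must have one row per decoded bin")
  if (Tn && (min(object@states) < 1L || max(object@states) > K))
    msg <- c(msg, "states must be indices in [1, K]")
  if (Tn && any(abs(rowSums(object@posteriors) - 1) > 1e-6))
    msg <- c(msg, "posterior rows must sum to 1")
  if (length(object@labeling) && length(object@labeling) != K)
    msg <- c(msg, "labeling must map every state index")
  if (length(msg)) msg else TRUE
})

#' Semantic labeling of fitted HMM states
#'
#' Maps state indices to the field's sleep/wake labels by ascending fitted
#' rate: S2 (deep sleep), S1 (light sleep), W1 and W2 (wake) for 4-state
#' fits; S2, S1, W for 3-state fits.
#'
#' @slot labels character vector, one label per state index.
#' @slot lambdas fitted rates the labeling was derived from.
#' @slot reference reference rates used for the nearest-match cross-check.
#' @slot warnings labeling warnings (e.g. ordering/nearest-match conflict).
#' @export
setClass("StateLabeling",
  representation(labels = "character", lambdas = "numeric",
                 reference = "numeric", warnings = "character"))

setValidity("StateLabeling", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@lambdas))
    msg <- c(msg, "one label per state is required")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Best-fit-per-K model selection result
#'
#' @slot fits named list (by K) of best [FitResult-class] over restarts.
#' @slot bicTable data.frame with columns K, logLik, bic.
#' @slot selectedK the BIC-minimizing state count (ties to smaller K).
#' @slot nRestarts restarts used per K.
#' @export
setClass("SelectionResult",
  representation(fits = "list", bicTable = "data.frame",
                 selectedK = "integer", nRestarts = "integer"))

#' Stimulus-delivery protocol for arousal assays
#'
#' @slot times POSIXct stimulus times, strictly increasing, each aligned to
#'   a 1-min bin boundary.
#' @slot responseWindow seconds after the stimulus scanned for movement.
#' @slot baselineOffset seconds before the stimulus at which the baseline
#'   bin starts (default 120: the bin starting 2 min before).
#' @slot interStimulus nominal seconds between stimuli.
#' @export
setClass("StimulusProtocol",
  representation(times = "POSIXct", responseWindow = "numeric",
                 baselineOffset = "numeric", interStimulus = "numeric"))

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (length(object@times) < 1L) msg <- c(msg, "at least one stimulus")
  if (length(object@times) > 1L && any(diff(as.numeric(object@times)) <= 0))
    msg <- c(msg, "stimulus times must be strictly increasing")
  if (object@responseWindow >= object@interStimulus)
    msg <- c(msg, "response window must be shorter than the interval")
  if (length(msg)) msg else TRUE
})

#' Ground-truth generative description of a synthetic cohort
#'
#' Describes a circadian, time-inhomogeneous hidden Markov generator: one
#' transition matrix for light (day) bins and one for dark (night) bins
#' over a shared set of labeled states, per-state base rates, lognormal
#' per-fish rate jitter, and optional zero-inflation, arousal-response and
#' rebound parameters.
#'
#' @slot labels state labels, ascending activity order.
#' @slot lambdas base per-state rates (s/min).
#' @slot dayTransitions,nightTransitions row-stochastic matrices indexed
#'   like \code{labels}.
#' @slot jitterSd lognormal sd of the per-fish multiplicative rate jitter.
#' @slot zipWeights optional per-state zero-inflation weights (length 0 =
#'   plain Poisson).
#' @slot responseProbs optional per-state stimulus-response probabilities.
#' @slot reboundBoost post-deprivation increment to the deep-sleep
#'   self-transition (renormalized).
#' @slot schedule [LightSchedule-class] defining the protocol.
#' @export
setClass("SyntheticSpec",
  representation(labels = "character", lambdas = "numeric",
                 dayTransitions = "matrix", nightTransitions = "matrix",
                 jitterSd = "numeric", zipWeights = "numeric",
                 responseProbs = "numeric", reboundBoost = "numeric",
                 schedule = "LightSchedule"))

setValidity("SyntheticSpec", function(object) {
  K <- length(object@labels)
  msg <- character()
  if (length(object@lambdas) != K || any(object@lambdas <= 0))
    msg <- c(msg, "lambdas must be positive, one per label")
  for (nm in c("dayTransitions", "nightTransitions")) {
    A <- slot(object, nm)
    if (!all(dim(A) == c(K, K)) || any(A < 0) ||
        any(abs(rowSums(A) - 1) > 1e-9))
      msg <- c(msg, paste(nm, "must be a row-stochastic K x K matrix"))
  }
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (length(object@responseProbs) &&
      (length(object@responseProbs) != K ||
       any(object@responseProbs < 0) || any(object@responseProbs > 1)))
    msg <- c(msg, "responseProbs must be in [0, 1], one per label")
  if (length(msg)) msg else TRUE
})
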