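#' @include AllClasses.R
NULL

#' Accessors for sleepHMM classes
#'
#' Small accessor family: \code{fishId()} and \code{activityValues()} for
#' traces, \code{binStarts()} for bin start times, \code{nBins()} for trace
#' length, \code{hmmK()}, \code{initialProbs()}, \code{transitionMatrix()},
#' \code{stateRates()} and \code{zeroWeights()} for model parameters,
#' \code{statePath()}, \code{statePosteriorMatrix()} and
#' \code{stateLabels()} for decoded sequences and labelings, and
#' \code{cohortTraces()} / \code{cohortLabel()} for cohorts.
#'
#' @param x an object of the corresponding class.
#' @return The slot value; \code{binStarts()} returns POSIXct bin start
#'   times and \code{nBins()} the number of 1-min bins.
#' @name accessors
#' @aliases fishId activityValues binStarts nBins hmmK initialProbs
#'   transitionMatrix stateRates zeroWeights statePath
#'   statePosteriorMatrix stateLabels cohortTraces cohortLabel
#'   scheduleIntervals
NULL

#' @rdname accessors
#' @export
setGeneric("fishId", function(x) standardGeneric("fishId"))
#' @rdname accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))
#' @rdname accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("hmmK", function(x) standardGeneric("hmmK"))
#' @rdname accessors
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix",
           function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateRates", function(x) standardGeneric("stateRates"))
#' @rdname accessors
#' @export
setGeneric("zeroWeights", function(x) standardGeneric("zeroWeights"))
#' @rdname accessors
#' @export
setGeneric("statePath", function(x) standardGeneric("statePath"))
#' @rdname accessors
#' @export
setGeneric("statePosteriorMatrix",
           function(x) standardGeneric("statePosteriorMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("cohortTraces", function(x) standardGeneric("cohortTraces"))
#' @rdname accessors
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))
#' @rdname accessors
#' @export
setGeneric("scheduleIntervals",
           function(x) standardGeneric("scheduleIntervals"))

#' @rdname accessors
setMethod("fishId", "ActivityTrace", function(x) x@fishId)
#' @rdname accessors
setMethod("fishId", "RawActivitySeries", function(x) x@fishId)
#' @rdname accessors
setMethod("activityValues", "ActivityTrace", function(x) x@values)
#' @rdname accessors
setMethod("activityValues", "RawActivitySeries", function(x) x@values)
#' @rdname accessors
setMethod("nBins", "ActivityTrace", function(x) length(x@values))
#' @rdname accessors
setMethod("binStarts", "ActivityTrace", function(x)
  x@startClock + 60 * (seq_along(x@values) - 1L))
#' @rdname accessors
setMethod("hmmK", "HMMParams", function(x) x@K)
#' @rdname accessors
setMethod("hmmK", "FitResult", function(x) x@params@K)
#' @rdname accessors
setMethod("initialProbs", "HMMParams", function(x) x@initial)
#' @rdname accessors
setMethod("transitionMatrix", "HMMParams", function(x) x@transitions)
#' @rdname accessors
setMethod("transitionMatrix", "FitResult",
          function(x) x@params@transitions)
#' @rdname accessors
setMethod("stateRates", "HMMParams", function(x) x@lambdas)
#' @rdname accessors
setMethod("stateRates", "FitResult", function(x) x@params@lambdas)
#' @rdname accessors
setMethod("zeroWeights", "HMMParams", function(x) x@zeroWeights)
#' @rdname accessors
setMethod("statePath", "StateSequence", function(x) x@states)
#' @rdname accessors
setMethod("statePosteriorMatrix", "StateSequence",
          function(x) x@posteriors)
#' @rdname accessors
setMethod("stateLabels", "StateSequence", function(x) x@labeling)
#' @rdname accessors
setMethod("stateLabels", "StateLabeling", function(x) x@labels)
#' @rdname accessors
setMethod("cohortTraces", "Cohort", function(x) x@traces)
#' @rdname accessors
setMethod("cohortLabel", "Cohort", function(x) x@label)
#' @rdname accessors
setMethod("scheduleIntervals", "LightSchedule",
          function(x) x@intervals)

setMethod("show", "ActivityTrace", function(object) {
  cat("ActivityTrace for fish", object@fishId, "\n")
  cat("  ", length(object@values), " one-minute bins from ",
      format(object@startClock, "%Y-%m-%d %H:%M", tz = "UTC"),
      " UTC\n", sep = "")
  cat("  mean activity ", round(mean(object@values), 2), " s/min; ",
      sum(object@values == 0L), " zero bins\n", sep = "")
})

setMethod("show", "LightSchedule", function(object) {
  iv <- object@intervals
  cat("LightSchedule with", nrow(iv), "intervals\n")
  print(utils::head(iv, 6L))
  if (nrow(iv) > 6L) cat("  ...", nrow(iv) - 6L, "more\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort '", object@label, "': ", length(object@traces),
      " fish\n", sep = "")
})

setMethod("show", "HMMParams", function(object) {
  cat("HMMParams: K =", object@K,
      if (length(object@zeroWeights)) "(zero-inflated Poisson)"
      else "(Poisson)", "\n")
  cat("  lambdas (s/min):",
      paste(signif(object@lambdas, 3), collapse = ", "), "\n")
  cat("  self-transitions:",
      paste(signif(diag(object@transitions), 3), collapse = ", "), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult: K =", object@params@K, " logLik =",
      round(object@logLik, 2), "\n")
  cat("  ", object@nIter, " EM iterations; converged: ",
      object@converged, "; seed ", object@seed, "\n", sep = "")
})

setMethod("show", "StateSequence", function(object) {
  K <- ncol(object@posteriors)
  cat("StateSequence:", length(object@states), "bins,", K, "states\n")
  if (length(object@labeling)) {
    occ <- table(factor(object@labeling[object@states],
                        levels = object@labeling))
    cat("  decoded occupancy:",
        paste(names(occ), signif(as.numeric(occ) / length(object@states),
                                 3), collapse = ", "), "\n")
  }
})

setMethod("show", "StateLabeling", function(object) {
  cat("StateLabeling:",
      paste(seq_along(object@labels), object@labels, sep = "->",
            collapse = ", "), "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: selected K* =", object@selectedK, "over K in {",
      paste(object@bicTable$K, collapse = ", "), "}\n")
  print(object@bicTable, row.names = FALSE)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", length(object@labels), "states (",
      paste(object@labels, collapse = ", "), ")\n")
  cat("  base rates:", paste(signif(object@lambdas, 3), collapse = ", "),
      "s/min; jitter sd", object@jitterSd, "\n")
})

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol:", length(object@times), "stimuli every",
      object@interStimulus, "s; response window",
      object@responseWindow, "s\n")
})
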