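#' @include selection.R activity.R
NULL

#' Construct a stimulus protocol
#'
#' @param times POSIXct stimulus times (each on a 1-min bin boundary).
#' @param responseWindow seconds after each stimulus scanned for movement
#'   (default 2).
#' @param baselineOffset seconds before the stimulus at which the
#'   baseline bin starts (default 120).
#' @param interStimulus nominal inter-stimulus interval in seconds
#'   (default 300 = every 5 minutes).
#' @return A [StimulusProtocol-class].
#' @export
StimulusProtocol <- function(times, responseWindow = 2,
                             baselineOffset = 120, interStimulus = 300) {
  new("StimulusProtocol", times = .posixct(times),
      responseWindow = as.numeric(responseWindow),
      baselineOffset = as.numeric(baselineOffset),
      interStimulus = as.numeric(interStimulus))
}

#' Pooled (concatenated) multi-fish HMM fit
#'
#' Fits a single shared HMM to all fish by pooling EM sufficient
#' statistics across traces (no transitions across fish boundaries).
#' Used for single-night recordings, which are too short for reliable
#' per-fish fitting.
#'
#' @param traces [Cohort-class] or list of traces.
#' @param K number of states (default 4).
#' @param nRestarts restarts.
#' @param baseSeed seed.
#' @param ... passed to [fitEM()].
#' @return A [FitResult-class].
#' @export
concatenatedFit <- function(traces, K = 4L, nRestarts = 20L,
                            baseSeed = 1L, ...) {
  fitMultistart(traces, K, nRestarts = nRestarts, baseSeed = baseSeed,
                ...)
}

#' Exclude fish whose decoded path misses any state
#'
#' For a fair comparison of per-state response fractions, fish whose
#' decoded sequence does not visit every one of the K states at least
#' once are excluded.
#'
#' @param seqs list of [StateSequence-class], one per fish.
#' @param K number of states.
#' @return List with \code{retained} (indices), \code{excluded}
#'   (indices), and \code{counts} (per-fish number of distinct states
#'   visited).
#' @export
excludeIncompleteFish <- function(seqs, K) {
  counts <- vapply(seqs, function(s) length(unique(s@states)), integer(1))
  keep <- counts == K
  list(retained = which(keep), excluded = which(!keep), counts = counts)
}

#' State of the bin ending at each stimulus
#'
#' Bins are aligned so each stimulus falls exactly at the end of a 1-min
#' bin; the state decoded for that preceding bin is the fish's state at
#' the stimulus.  Stimuli arriving before one full bin has elapsed are
#' dropped with a warning; off-boundary stimulus times are an error.
#'
#' @param seq a [StateSequence-class] for one fish.
#' @param traceStart POSIXct start of the fish's binned trace.
#' @param protocol a [StimulusProtocol-class].
#' @return Integer vector of pre-stimulus state indices (NA = dropped),
#'   one per stimulus.
#' @export
prestimulusStates <- function(seq, traceStart, protocol) {
  offs <- as.numeric(protocol@times) - as.numeric(.posixct(traceStart))
  .stop_if(any(abs(offs %% 60) > 1e-6 & abs(offs %% 60 - 60) > 1e-6),
           "stimulus times must lie on 1-min bin boundaries; re-align bins")
  bin <- as.integer(round(offs / 60))  # bin ending at the stimulus
  out <- rep(NA_integer_, length(bin))
  ok <- bin >= 1L & bin <= length(seq@states)
  if (any(bin < 1L))
    warning(sum(bin < 1L),
            " stimulus(es) before one full bin elapsed; dropped")
  out[ok] <- seq@states[bin[ok]]
  out
}

# Per-(fish, stimulus) event table: pre-stimulus state/activity, response
# detection, and baseline-bin state/movement detection.
.stimulus_events <- function(raws, seqs, labeling, protocol,
                             activeThreshold = 0) {
  labels <- stateLabels(labeling)
  do.call(rbind, lapply(seq_along(raws), function(i) {
    raw <- raws[[i]]
    rate <- raw@sampleRate
    t0 <- as.numeric(raw@startClock)
    moved_in <- function(from, len) {
      # any suprathreshold sample in (from, from + len] seconds from start
      a <- floor(from * rate) + 1L
      b <- floor((from + len) * rate)
      if (a < 1L || b > length(raw@values)) return(NA)
      any(raw@values[a:b] > activeThreshold)
    }
    st <- prestimulusStates(seqs[[i]], raw@startClock, protocol)
    offs <- as.numeric(protocol@times) - t0
    base_bin <- as.integer(round((offs - protocol@baselineOffset) / 60)) +
      1L
    ok_base <- base_bin >= 1L & base_bin <= length(seqs[[i]]@states)
    data.frame(
      fish = raw@fishId, stimulus = seq_along(offs),
      state = ifelse(is.na(st), NA_character_, labels[st]),
      responded = vapply(offs, moved_in, NA,
                         len = protocol@responseWindow),
      baselineState = ifelse(ok_base,
                             labels[seqs[[i]]@states[pmax(base_bin, 1L)]],
                             NA_character_),
      baselineMoved = vapply(offs - protocol@baselineOffset, moved_in,
                             NA, len = protocol@responseWindow),
      prestimActivity = vapply(offs, function(o) {
        a <- floor((o - 60) * rate) + 1L
        b <- floor(o * rate)
        if (a < 1L || b > length(raw@values)) return(NA_integer_)
        secs <- floor((seq(a, b) - 1) / rate)
        as.integer(sum(tapply(raw@values[a:b] > activeThreshold, secs,
                              any)))
      }, NA_integer_),
      stringsAsFactors = FALSE)
  }))
}

#' Per-state arousal response fractions with baseline correction
#'
#' For each state, the fraction of stimuli followed by any movement
#' within the response window, minus the baseline probability that a fish
#' in that state moves in an equivalent window without a stimulus.  The
#' baseline detector scans the first seconds (same window length) of the
#' bin starting \code{baselineOffset} seconds before the stimulus,
#' conditioned on that baseline bin's own decoded state.
#'
#' @param raws list of [RawActivitySeries-class] (retained fish only).
#' @param seqs list of [StateSequence-class], aligned with \code{raws}.
#' @param labeling shared [StateLabeling-class].
#' @param protocol a [StimulusProtocol-class].
#' @param activeThreshold movement-detection threshold (as in
#'   [binActivity()]).
#' @return data.frame per state: \code{state}, \code{n} (classified
#'   stimuli), \code{raw}, \code{baselineN}, \code{baseline},
#'   \code{corrected} (= raw - baseline; may be negative), plus a
#'   \code{"dropped"} attribute counting unclassifiable stimuli.
#' @export
responseFractions <- function(raws, seqs, labeling, protocol,
                              activeThreshold = 0) {
  ev <- .stimulus_events(raws, seqs, labeling, protocol, activeThreshold)
  labels <- stateLabels(labeling)
  out <- do.call(rbind, lapply(labels, function(l) {
    sel <- !is.na(ev$state) & ev$state == l & !is.na(ev$responded)
    selb <- !is.na(ev$baselineState) & ev$baselineState == l &
      !is.na(ev$baselineMoved)
    raw_frac <- if (any(sel)) mean(ev$responded[sel]) else NA_real_
    base_frac <- if (any(selb)) mean(ev$baselineMoved[selb]) else NA_real_
    data.frame(state = l, n = sum(sel), raw = raw_frac,
               baselineN = sum(selb), baseline = base_frac,
               corrected = raw_frac - base_frac)
  }))
  attr(out, "dropped") <- sum(is.na(ev$state) | is.na(ev$responded))
  out
}

#' Response fractions at a fixed pre-stimulus activity level
#'
#' Restricts the arousal analysis to stimuli whose pre-stimulus bin has
#' exactly \code{activityValue} seconds of activity, splitting by decoded
#' state.  Because state assignment is context-dependent, bins with
#' identical activity can carry different states; differing response
#' fractions at matched activity demonstrate that the states carry
#' information beyond the activity level itself.
#'
#' @inheritParams responseFractions
#' @param activityValue pre-stimulus bin activity (s/min) to condition
#'   on.
#' @return data.frame per state present among qualifying bins:
#'   \code{state}, \code{n}, \code{splitFraction} (share of qualifying
#'   bins), \code{raw}, \code{corrected} (raw minus the state's overall
#'   baseline).  Zero qualifying stimuli yield an empty data.frame.
#' @export
matchedActivityComparison <- function(raws, seqs, labeling, protocol,
                                      activityValue,
                                      activeThreshold = 0) {
  ev <- .stimulus_events(raws, seqs, labeling, protocol, activeThreshold)
  overall <- responseFractions(raws, seqs, labeling, protocol,
                               activeThreshold)
  sel <- !is.na(ev$state) & !is.na(ev$prestimActivity) &
    ev$prestimActivity == activityValue & !is.na(ev$responded)
  if (!any(sel)) return(data.frame(state = character(0), n = integer(0),
                                   splitFraction = numeric(0),
                                   raw = numeric(0),
                                   corrected = numeric(0)))
  sub <- ev[sel, ]
  states <- unique(sub$state)
  do.call(rbind, lapply(states, function(l) {
    s <- sub$state == l
    base <- overall$baseline[overall$state == l]
    data.frame(state = l, n = sum(s),
               splitFraction = mean(sub$state == l),
               raw = mean(sub$responded[s]),
               corrected = mean(sub$responded[s]) - base)
  }))
}
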