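#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an ActivityTrace
#'
#' Builds a 1-min binned activity trace.  Non-integer inputs are rounded to
#' the nearest integer and values outside [0, 60] are clipped, with a
#' warning in both cases: the hidden Markov layer treats observations as
#' Poisson counts of active seconds per minute, while real pixel-derived
#' data may be fractional.
#'
#' @param fishId identifier string.
#' @param values activity values (seconds active per minute).
#' @param startClock POSIXct start of the first bin (default: lights-on at
#'   09:00 on a reference date).
#' @return An [ActivityTrace-class] object.
#' @export
ActivityTrace <- function(fishId, values, startClock = .default_start()) {
  .stop_if(length(values) < 1L, "values must contain at least one bin")
  v <- as.numeric(values)
  .stop_if(anyNA(v), "activity values must not be missing")
  if (any(abs(v - round(v)) > 1e-9)) {
    warning("non-integer activity values rounded to nearest integer")
    v <- round(v)
  }
  if (any(v < 0) || any(v > 60)) {
    warning("activity values outside [0, 60] clipped")
    v <- pmin(pmax(v, 0), 60)
  }
  new("ActivityTrace", fishId = as.character(fishId),
      startClock = .posixct(startClock), binWidth = 60,
      values = as.integer(round(v)))
}

#' Construct a RawActivitySeries
#'
#' @param fishId identifier string.
#' @param values per-sample non-negative activity magnitudes.
#' @param sampleRate samples per second.
#' @param startClock POSIXct time of the first sample.
#' @return A [RawActivitySeries-class] object.
#' @export
RawActivitySeries <- function(fishId, values, sampleRate = 1,
                              startClock = .default_start()) {
  new("RawActivitySeries", fishId = as.character(fishId),
      startClock = .posixct(startClock),
      sampleRate = as.numeric(sampleRate), values = as.numeric(values))
}

#' Construct a LightSchedule
#'
#' @param start,end POSIXct (or coercible) interval boundaries.
#' @param condition per-interval lighting condition: \code{light},
#'   \code{dark}, \code{subjective_day} or \code{subjective_night}.
#' @return A [LightSchedule-class] object.
#' @export
LightSchedule <- function(start, end, condition) {
  iv <- data.frame(start = .posixct(start), end = .posixct(end),
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  new("LightSchedule", intervals = iv)
}

#' Construct a Cohort
#'
#' @param traces list of [ActivityTrace-class] objects.
#' @param label group label.
#' @param metadata optional per-fish annotation data.frame.
#' @return A [Cohort-class] object.
#' @export
Cohort <- function(traces, label = "cohort",
                   metadata = data.frame(row.names = NULL)) {
  new("Cohort", label = as.character(label), traces = traces,
      metadata = metadata)
}

#' Default 14:10 light:dark schedule
#'
#' White lights on from 09:00 to 23:00 (14 h light), off from 23:00 to
#' 09:00 (10 h dark), repeated for \code{days} days starting at the
#' recording start.
#'
#' @param days number of 24-h cycles (default 2, a 48-h recording).
#' @param start recording start time (default: lights-on 09:00).
#' @param subjective if TRUE, build the free-running constant-dark variant
#'   with conditions \code{subjective_day}/\code{subjective_night} on the
#'   same phase.
#' @return A [LightSchedule-class] object.
#' @export
defaultSchedule <- function(days = 2, start = .default_start(),
                            subjective = FALSE) {
  start <- .posixct(start)
  day_cond <- if (subjective) "subjective_day" else "light"
  night_cond <- if (subjective) "subjective_night" else "dark"
  starts <- ends <- .posixct(character(0))
  cond <- character(0)
  for (d in seq_len(days) - 1L) {
    s0 <- start + d * 86400
    starts <- c(starts, s0, s0 + 14 * 3600)
    ends <- c(ends, s0 + 14 * 3600, s0 + 24 * 3600)
    cond <- c(cond, day_cond, night_cond)
  }
  LightSchedule(starts, ends, cond)
}

#' Sleep-deprivation lighting schedule
#'
#' A 48-h schedule in which the second night's lights stay on for its first
#' 6 h (light-forced wakefulness) and turn off only for the final 4 h, the
#' rebound-sleep window.
#'
#' @param start recording start time (default: lights-on 09:00).
#' @return A [LightSchedule-class] object.
#' @export
sleepDeprivationSchedule <- function(start = .default_start()) {
  start <- .posixct(start)
  h <- 3600
  LightSchedule(
    start = start + c(0, 14, 24, 38, 44) * h,
    end   = start + c(14, 24, 38, 44, 48) * h,
    condition = c("light", "dark", "light", "light", "dark"))
}

#' Bin a raw activity series into 1-minute seconds-active counts
#'
#' Each 1-min bin receives the number of whole seconds within it that
#' contain at least one sample with magnitude above
#' \code{activeThreshold}.  Any trailing partial minute is discarded.
#'
#' @param raw a [RawActivitySeries-class].
#' @param activeThreshold magnitude above which a sample counts as
#'   movement (default 0: any positive magnitude).
#' @return An [ActivityTrace-class] with values in [0, 60].
#' @export
binActivity <- function(raw, activeThreshold = 0) {
  stopifnot(is(raw, "RawActivitySeries"))
  .stop_if(activeThreshold < 0, "activeThreshold must be >= 0")
  n <- length(raw@values)
  rate <- raw@sampleRate
  n_min <- floor(n / (60 * rate))
  .stop_if(n_min < 1, "series shorter than one full minute")
  n_use <- n_min * 60 * rate
  active <- raw@values[seq_len(n_use)] > activeThreshold
  # second index of each sample, then: second active iff any active sample
  sec <- floor((seq_len(n_use) - 1) / rate)
  sec_active <- tapply(active, sec, any)
  minute <- floor(as.numeric(names(sec_active)) / 60)
  counts <- as.integer(tapply(sec_active, minute, sum))
  ActivityTrace(raw@fishId, counts, raw@startClock)
}

#' Label trace bins as day or night
#'
#' Each bin is assigned the condition of the schedule interval containing
#' its start time (intervals are half-open \code{[start, end)});
#' \code{light}/\code{subjective_day} map to \code{day} and
#' \code{dark}/\code{subjective_night} to \code{night}.
#'
#' @param trace an [ActivityTrace-class].
#' @param schedule a [LightSchedule-class] covering every bin start.
#' @return Character vector of \code{"day"}/\code{"night"}, length
#'   \code{nBins(trace)}.
#' @export
labelBins <- function(trace, schedule) {
  stopifnot(is(trace, "ActivityTrace"), is(schedule, "LightSchedule"))
  iv <- schedule@intervals
  ts <- as.numeric(binStarts(trace))
  idx <- findInterval(ts + 1e-6, as.numeric(iv$start))
  bad <- idx < 1L | ts + 1e-6 >= as.numeric(iv$end)[pmax(idx, 1L)]
  .stop_if(any(bad), sprintf("bin %d (start %s) not covered by schedule",
                             which(bad)[1L],
                             format(binStarts(trace)[which(bad)[1L]])))
  cond <- iv$condition[idx]
  ifelse(cond %in% c("light", "subjective_day"), "day", "night")
}

#' Conventional sleep: one-minute immobility
#'
#' The conventional behavioral definition of larval zebrafish sleep: any
#' 1-min bin with zero locomotor activity is a sleep minute.
#'
#' @param trace an [ActivityTrace-class].
#' @return List with \code{flags} (logical per bin) and
#'   \code{totalMinutes}.
#' @export
conventionalSleep <- function(trace) {
  stopifnot(is(trace, "ActivityTrace"))
  flags <- trace@values == 0L
  list(flags = flags, totalMinutes = sum(flags))
}
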