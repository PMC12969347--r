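#' @include activity.R hmm.R
NULL

.LABELS4 <- c("S2", "S1", "W1", "W2")
.LABELS3 <- c("S2", "S1", "W")

.named_matrix <- function(rows, labels) {
  A <- do.call(rbind, rows)
  dimnames(A) <- list(labels, labels)
  A
}

# Package-constant generator matrices (not fitted values): the night
# matrix puts ~80% of long-run mass on the sleep states and the day
# matrix ~75% on the wake states, with self-transitions >= 0.85, so that
# simulated bout and proportion patterns show the qualitative circadian
# architecture of real recordings.
.WT_NIGHT <- .named_matrix(list(
  c(0.93, 0.05, 0.015, 0.005),
  c(0.06, 0.90, 0.025, 0.015),
  c(0.06, 0.08, 0.85, 0.01),
  c(0.03, 0.05, 0.07, 0.85)), .LABELS4)

.WT_DAY <- .named_matrix(list(
  c(0.86, 0.06, 0.06, 0.02),
  c(0.02, 0.85, 0.09, 0.04),
  c(0.01, 0.04, 0.88, 0.07),
  c(0.01, 0.02, 0.07, 0.90)), .LABELS4)

#' Construct a synthetic-cohort generative description
#'
#' @param lambdas base per-state rates (s/min), ascending.
#' @param dayTransitions,nightTransitions row-stochastic matrices.
#' @param labels state labels.
#' @param jitterSd lognormal sd of per-fish multiplicative rate jitter
#'   (default 0.1: modest individual variability).
#' @param zipWeights optional per-state zero-inflation weights.
#' @param responseProbs optional per-state stimulus-response
#'   probabilities.
#' @param reboundBoost post-deprivation deep-sleep self-transition
#'   increment (default 0.05).
#' @param schedule [LightSchedule-class] (default 48-h 14:10 LD).
#' @return A [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(lambdas, dayTransitions, nightTransitions,
                          labels = .LABELS4, jitterSd = 0.1,
                          zipWeights = numeric(0),
                          responseProbs = numeric(0),
                          reboundBoost = 0.05,
                          schedule = defaultSchedule()) {
  new("SyntheticSpec", labels = labels, lambdas = as.numeric(lambdas),
      dayTransitions = dayTransitions,
      nightTransitions = nightTransitions,
      jitterSd = as.numeric(jitterSd),
      zipWeights = as.numeric(zipWeights),
      responseProbs = as.numeric(responseProbs),
      reboundBoost = as.numeric(reboundBoost), schedule = schedule)
}

# Shift probability mass within row `from`: move `delta` from column
# `take` to column `give`, clamping at 0, then renormalize.
.shift_mass <- function(A, from, take, give, delta) {
  d <- min(delta, A[from, take])
  A[from, take] <- A[from, take] - d
  A[from, give] <- A[from, give] + d
  A / rowSums(A)
}

#' Synthetic-cohort presets emulating the study conditions
#'
#' Named generator specifications.  \code{wt} is the baseline 4-state
#' circadian generator built on the group-level wild-type rates (0.02,
#' 1.18, 4.07, 7.49 s/min).  The manipulation presets perturb the wt
#' transition matrices to produce each manipulation's directional
#' state-proportion changes (directional, not quantitative):
#' \describe{
#'   \item{aanat2_like}{melatonin-deficient: night deep sleep (S2) down,
#'     light sleep (S1) up; day unchanged.}
#'   \item{melatonin_treated}{exogenous melatonin: daytime W2 suppressed
#'     in favor of W1/S states; night S1 reduced, wake states up.}
#'   \item{tph2_like}{raphe-serotonin-deficient: night S2 down, S1 up,
#'     with globally higher rates.}
#'   \item{quipazine_like}{serotonin agonist: night S2 up, S1 down, with
#'     lower rates.}
#'   \item{dbh_like}{noradrenaline-deficient: S2 up in both periods,
#'     wake maintenance down.}
#'   \item{prazosin_like}{alpha1-adrenergic antagonist: like dbh_like.}
#'   \item{constant_dark}{free-running: a 3-state generator (S2, S1, W)
#'     under a subjective-day/night schedule - the high-activity wake
#'     state requires light-driven arousal and is absent.}
#' }
#'
#' @param name preset name.
#' @return A [SyntheticSpec-class].
#' @export
sleepPreset <- function(name = c("wt", "constant_dark", "aanat2_like",
                                 "melatonin_treated", "tph2_like",
                                 "quipazine_like", "dbh_like",
                                 "prazosin_like")) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset '", name[1L],
                          "'; available: wt, constant_dark, aanat2_like, ",
                          "melatonin_treated, tph2_like, quipazine_like, ",
                          "dbh_like, prazosin_like", call. = FALSE))
  lam <- c(0.02, 1.18, 4.07, 7.49)
  day <- .WT_DAY
  night <- .WT_NIGHT
  switch(name,
    wt = SyntheticSpec(lam, day, night,
                       responseProbs = c(0.10, 0.30, 0.60, 0.80)),
    aanat2_like = {
      night <- .shift_mass(night, "S2", "S2", "S1", 0.08)
      night <- .shift_mass(night, "S1", "S2", "S1", 0.05)
      SyntheticSpec(lam, day, night)
    },
    tph2_like = {
      night <- .shift_mass(night, "S2", "S2", "S1", 0.07)
      night <- .shift_mass(night, "S1", "S2", "S1", 0.05)
      SyntheticSpec(lam * c(1.5, 1.15, 1.1, 1.1), day, night)
    },
    quipazine_like = {
      night <- .shift_mass(night, "S2", "S1", "S2", 0.03)
      night <- .shift_mass(night, "S1", "S1", "S2", 0.10)
      SyntheticSpec(lam * c(0.8, 0.85, 0.9, 0.9), day, night)
    },
    melatonin_treated = {
      day <- .shift_mass(day, "W2", "W2", "W1", 0.12)
      day <- .shift_mass(day, "W1", "W1", "S1", 0.04)
      night <- .shift_mass(night, "S1", "S1", "W1", 0.05)
      night <- .shift_mass(night, "S1", "S1", "W2", 0.02)
      SyntheticSpec(lam, day, night)
    },
    dbh_like = ,
    prazosin_like = {
      night <- .shift_mass(night, "S2", "S1", "S2", 0.03)
      night <- .shift_mass(night, "S1", "S1", "S2", 0.08)
      day <- .shift_mass(day, "W1", "W1", "S2", 0.05)
      day <- .shift_mass(day, "W2", "W2", "S2", 0.05)
      day <- .shift_mass(day, "S2", "S1", "S2", 0.04)
      SyntheticSpec(lam, day, night)
    },
    constant_dark = {
      # 3-state free-running generator: subjective day keeps a mild
      # W bias, subjective night a mild sleep bias.
      day3 <- .named_matrix(list(
        c(0.88, 0.07, 0.05),
        c(0.04, 0.86, 0.10),
        c(0.02, 0.08, 0.90)), .LABELS3)
      night3 <- .named_matrix(list(
        c(0.93, 0.05, 0.02),
        c(0.08, 0.87, 0.05),
        c(0.05, 0.10, 0.85)), .LABELS3)
      SyntheticSpec(c(0.02, 1.18, 4.07), day3, night3,
                    labels = .LABELS3,
                    schedule = defaultSchedule(subjective = TRUE))
    })
}

# Period label per bin for an arbitrary schedule, given the trace start.
.schedule_periods <- function(schedule, start, nMinutes) {
  dummy <- ActivityTrace("dummy", integer(nMinutes) ,
                         startClock = start)
  labelBins(dummy, schedule)
}

# Simulate one hidden path under a per-bin matrix selector.
.simulate_path <- function(matrices, selector, nMinutes) {
  K <- nrow(matrices[[1L]])
  path <- integer(nMinutes)
  path[1L] <- sample.int(K, 1L,
    prob = stationaryDistribution(matrices[[selector[1L]]]))
  for (t in seq_len(nMinutes - 1L))
    path[t + 1L] <- sample.int(K, 1L,
      prob = matrices[[selector[t]]][path[t], ])
  path
}

.emit_counts <- function(path, lambdas, zipWeights) {
  x <- stats::rpois(length(path), lambdas[path])
  if (length(zipWeights)) {
    zero <- stats::runif(length(path)) < zipWeights[path]
    x[zero] <- 0L
  }
  pmin(x, 60L)
}

#' Generate a synthetic circadian cohort
#'
#' Per fish: rates are jittered by a lognormal factor (individual
#' variability), a hidden state path is drawn from the day matrix during
#' light bins and the night matrix during dark bins (switching at the
#' boundaries), and observations are Poisson (or zero-inflated Poisson)
#' counts clipped to 60 s/min.  Fully reproducible from \code{seed}.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nFish cohort size.
#' @param duration recording length in minutes (default 2880 = 48 h;
#'   must be covered by the spec's schedule).
#' @param seed base seed.
#' @param label cohort label.
#' @return List with \code{cohort} ([Cohort-class]), \code{truth} (per
#'   fish: hidden path, jittered rates), \code{periods} (per-bin
#'   day/night), \code{schedule}.
#' @export
generateCohort <- function(spec, nFish, duration = 2880L, seed = 1L,
                           label = "synthetic") {
  stopifnot(is(spec, "SyntheticSpec"))
  .stop_if(duration != round(duration), "duration must be whole minutes")
  start <- spec@schedule@intervals$start[1L]
  periods <- .schedule_periods(spec@schedule, start, duration)
  matrices <- list(day = spec@dayTransitions,
                   night = spec@nightTransitions)
  traces <- vector("list", nFish)
  truth <- vector("list", nFish)
  for (i in seq_len(nFish)) {
    fid <- sprintf("fish%03d", i)
    res <- withSeed(deriveSeed(seed, i), {
      lam <- spec@lambdas *
        exp(stats::rnorm(length(spec@lambdas), 0, spec@jitterSd))
      path <- .simulate_path(matrices, periods, duration)
      x <- .emit_counts(path, lam, spec@zipWeights)
      list(lam = lam, path = path, x = x)
    })
    traces[[i]] <- ActivityTrace(fid, res$x, start)
    truth[[i]] <- list(fishId = fid, path = res$path,
                       labels = spec@labels[res$path],
                       lambdas = res$lam)
  }
  list(cohort = Cohort(traces, label = label), truth = truth,
       periods = periods, schedule = spec@schedule)
}

#' Generate a sleep-deprivation cohort
#'
#' A 48-h protocol in which the second night's lights stay on for its
#' first 6 h (the path follows the day matrix: light-forced wakefulness)
#' and turn off for the final 4 h, during which the night matrix is used
#' with the deep-sleep self-transition incremented by the spec's rebound
#' boost (off-diagonal mass rescaled to keep the row stochastic) - a
#' phenomenological model of deprivation-induced deep-sleep rebound.
#'
#' @param spec a [SyntheticSpec-class] (4-state).
#' @param nFish cohort size.
#' @param seed base seed.
#' @return As [generateCohort()], plus \code{reboundWindow} (bin indices
#'   of the rebound window) and \code{boost}.
#' @export
generateSleepDeprivation <- function(spec, nFish, seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  schedule <- sleepDeprivationSchedule(
    spec@schedule@intervals$start[1L])
  duration <- 2880L
  start <- schedule@intervals$start[1L]
  periods <- .schedule_periods(schedule, start, duration)
  s2 <- which(spec@labels == "S2")
  rebound <- spec@nightTransitions
  # boost deep-sleep persistence: self-transition += boost, remaining
  # off-diagonal mass rescaled so the row stays stochastic
  self_new <- rebound[s2, s2] + spec@reboundBoost
  if (self_new >= 1) {
    message("rebound boost clipped to keep the row stochastic")
    self_new <- 1 - 1e-6
  }
  scale <- (1 - self_new) / (1 - rebound[s2, s2])
  rebound[s2, ] <- rebound[s2, ] * scale
  rebound[s2, s2] <- self_new
  # selector: day / night-1 / rebound window (last 4 h)
  sel <- ifelse(periods == "day", "day", "night")
  rb_bins <- (44L * 60L + 1L):(48L * 60L)
  sel[rb_bins] <- "rebound"
  matrices <- list(day = spec@dayTransitions,
                   night = spec@nightTransitions, rebound = rebound)
  traces <- vector("list", nFish)
  truth <- vector("list", nFish)
  for (i in seq_len(nFish)) {
    fid <- sprintf("fish%03d", i)
    res <- withSeed(deriveSeed(seed, i), {
      lam <- spec@lambdas *
        exp(stats::rnorm(length(spec@lambdas), 0, spec@jitterSd))
      path <- .simulate_path(matrices, sel, duration)
      x <- .emit_counts(path, lam, spec@zipWeights)
      list(lam = lam, path = path, x = x)
    })
    traces[[i]] <- ActivityTrace(fid, res$x, start)
    truth[[i]] <- list(fishId = fid, path = res$path,
                       labels = spec@labels[res$path],
                       lambdas = res$lam)
  }
  list(cohort = Cohort(traces, label = "sleep_deprivation"),
       truth = truth, periods = periods, schedule = schedule,
       reboundWindow = rb_bins, boost = spec@reboundBoost)
}

#' Generate a night-time arousal (stimulus-response) experiment
#'
#' Simulates 1-Hz raw activity for a single night: a hidden path at 1-min
#' resolution from the night matrix, per-minute Poisson activity spread
#' over random seconds within each minute, stimuli every 5 minutes on bin
#' boundaries, and at each stimulus a response event (movement within the
#' following 2 s) drawn with the pre-stimulus state's response
#' probability.  Spontaneous activity is independent of the stimuli.
#'
#' @param spec a [SyntheticSpec-class] with \code{responseProbs} set.
#' @param nFish number of fish.
#' @param nStimuli stimuli per fish (default 99).
#' @param seed base seed.
#' @return List with \code{raws} (list of [RawActivitySeries-class]),
#'   \code{protocol} ([StimulusProtocol-class]), \code{truth} (per fish:
#'   hidden path, response events), and \code{duration} (minutes).
#' @export
generateArousalExperiment <- function(spec, nFish, nStimuli = 99L,
                                      seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  .stop_if(length(spec@responseProbs) != length(spec@labels),
           "spec must set responseProbs for every state")
  duration <- 10L + 5L * nStimuli + 5L  # minutes; stimuli start at min 10
  start <- .posixct("2024-01-01 23:00:00")  # lights-off
  stim_min <- 10L + 5L * (seq_len(nStimuli) - 1L)
  stim_times <- start + 60 * stim_min
  night <- spec@nightTransitions
  raws <- vector("list", nFish)
  truth <- vector("list", nFish)
  for (i in seq_len(nFish)) {
    fid <- sprintf("fish%03d", i)
    res <- withSeed(deriveSeed(seed, i), {
      lam <- spec@lambdas *
        exp(stats::rnorm(length(spec@lambdas), 0, spec@jitterSd))
      path <- .simulate_path(list(night = night),
                             rep("night", duration), duration)
      counts <- .emit_counts(path, lam, spec@zipWeights)
      sec <- numeric(duration * 60L)
      for (m in seq_len(duration)) {
        k <- counts[m]
        if (k > 0L)
          sec[(m - 1L) * 60L + sample.int(60L, k)] <- 1
      }
      responded <- stats::runif(nStimuli) <
        spec@responseProbs[path[stim_min]]
      # response: movement within the 2 s following the stimulus
      for (j in which(responded))
        sec[stim_min[j] * 60L + sample.int(2L, 1L)] <- 1
      list(lam = lam, path = path, sec = sec, responded = responded)
    })
    raws[[i]] <- RawActivitySeries(fid, res$sec, sampleRate = 1,
                                   startClock = start)
    truth[[i]] <- list(fishId = fid, path = res$path,
                       labels = spec@labels[res$path],
                       lambdas = res$lam, responded = res$responded)
  }
  list(raws = raws,
       protocol = StimulusProtocol(stim_times), truth = truth,
       duration = duration)
}

#' Write / read a synthetic spec as a YAML-style config
#'
#' Keys: \code{labels}, \code{lambdas}, \code{day_transitions},
#' \code{night_transitions}, \code{jitter_sd}, \code{zip_weights},
#' \code{response_probs}, \code{rebound_boost}.
#'
#' @param spec a [SyntheticSpec-class].
#' @param path file path.
#' @return \code{writeSpecConfig}: \code{path} invisibly;
#'   \code{readSpecConfig}: a [SyntheticSpec-class] (with the default
#'   schedule; pass \code{subjective = TRUE} configs through presets).
#' @export
writeSpecConfig <- function(spec, path) {
  stopifnot(is(spec, "SyntheticSpec"))
  obj <- list(labels = spec@labels, lambdas = spec@lambdas,
              day_transitions = apply(spec@dayTransitions, 1, identity,
                                      simplify = FALSE),
              night_transitions = apply(spec@nightTransitions, 1,
                                        identity, simplify = FALSE),
              jitter_sd = spec@jitterSd,
              zip_weights = spec@zipWeights,
              response_probs = spec@responseProbs,
              rebound_boost = spec@reboundBoost)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSpecConfig
#' @export
readSpecConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  K <- length(obj$labels)
  mk <- function(rows) {
    A <- do.call(rbind, lapply(rows, unlist))
    dimnames(A) <- list(obj$labels, obj$labels)
    A
  }
  SyntheticSpec(unlist(obj$lambdas), mk(obj$day_transitions),
                mk(obj$night_transitions), labels = unlist(obj$labels),
                jitterSd = obj$jitter_sd,
                zipWeights = if (length(obj$zip_weights))
                  unlist(obj$zip_weights) else numeric(0),
                responseProbs = if (length(obj$response_probs))
                  unlist(obj$response_probs) else numeric(0),
                reboundBoost = obj$rebound_boost)
}
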