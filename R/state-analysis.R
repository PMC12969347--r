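#' @include hmm.R
NULL

# Group-level reference rates (s/min) used for the nearest-match
# cross-check when labeling fitted states.
.REFERENCE_LAMBDAS4 <- c(S2 = 0.02, S1 = 1.18, W1 = 4.07, W2 = 7.49)
.REFERENCE_LAMBDAS3 <- c(S2 = 0.02, S1 = 1.18, W = 4.07)

#' Semantically label fitted HMM states
#'
#' Four-state fits are labeled S2 (deep sleep), S1 (light sleep), W1 and
#' W2 (wake) in ascending fitted-rate order.  Three-state fits (seen under
#' free-running constant dark, where the high-activity wake state
#' disappears) are labeled S2, S1, W by the same ordering.  Both are
#' cross-checked against the group-level reference rates by nearest match;
#' an ordering/nearest-match conflict is recorded as a warning, not an
#' error.  K = 2 falls back to generic sleep-like/wake-like labels, other
#' K to ordinal labels.
#'
#' @param params an [HMMParams-class] (or [FitResult-class]).
#' @return A [StateLabeling-class] mapping state index to label.
#' @export
labelStates <- function(params) {
  if (is(params, "FitResult")) params <- params@params
  stopifnot(is(params, "HMMParams"))
  lam <- params@lambdas
  K <- params@K
  .stop_if(K > 1L && min(diff(sort(lam))) < 1e-6,
           "state rates tie within 1e-6; supply labels manually")
  warn <- character(0)
  ord <- order(lam)
  if (K == 4L || K == 3L) {
    ref <- if (K == 4L) .REFERENCE_LAMBDAS4 else .REFERENCE_LAMBDAS3
    labels <- character(K)
    labels[ord] <- names(ref)
    nearest <- names(ref)[vapply(lam, function(l)
      which.min(abs(l - ref)), integer(1))]
    if (!identical(nearest, labels))
      warn <- c(warn, paste0(
        "rate-order labels disagree with nearest-reference match (",
        paste(nearest, collapse = ","), " vs ",
        paste(labels, collapse = ","), ")"))
  } else if (K == 2L) {
    labels <- character(2)
    labels[ord] <- c("sleepLike", "wakeLike")
    warn <- c(warn, "K=2: generic sleep-like/wake-like labels assigned")
    warning(warn[length(warn)])
    ref <- numeric(0)
  } else {
    labels <- paste0("state", seq_len(K))
    warn <- c(warn, "K outside {2,3,4}: ordinal labels assigned")
    warning(warn[length(warn)])
    ref <- numeric(0)
  }
  if (K %in% c(3L, 4L)) ref <- if (K == 4L) .REFERENCE_LAMBDAS4
                                else .REFERENCE_LAMBDAS3
  new("StateLabeling", labels = labels, lambdas = lam,
      reference = ref, warnings = warn)
}

#' Long-run state occupancy
#'
#' The stationary distribution of the fitted transition matrix (its
#' dominant eigenvector), mapped through the semantic labeling.
#'
#' @param params an [HMMParams-class] or [FitResult-class].
#' @param labeling optional [StateLabeling-class] (computed via
#'   [labelStates()] when missing).
#' @param fallbackStates optional decoded path for reducible chains.
#' @return Named occupancy vector summing to 1.
#' @export
occupancy <- function(params, labeling = NULL, fallbackStates = NULL) {
  if (is(params, "FitResult")) params <- params@params
  if (is.null(labeling)) labeling <- labelStates(params)
  occ <- stationaryDistribution(params@transitions, fallbackStates)
  stats::setNames(occ, labeling@labels)
}

.label_seq <- function(seq, labeling) {
  labels <- if (is(labeling, "StateLabeling")) labeling@labels
            else as.character(labeling)
  labels[seq@states]
}

#' Time spent in each state by period
#'
#' Fraction of bins decoded to each label, split by day/night period;
#' fractions within a period sum to 1.
#'
#' @param seq a [StateSequence-class].
#' @param labeling a [StateLabeling-class] (or character label map).
#' @param periods per-bin \code{"day"}/\code{"night"} labels from
#'   [labelBins()].
#' @return data.frame with columns \code{period}, \code{label},
#'   \code{proportion}, \code{minutes}.
#' @export
stateProportions <- function(seq, labeling, periods) {
  .stop_if(length(periods) != length(seq@states),
           "periods and decoded states must have equal length")
  lab <- .label_seq(seq, labeling)
  labels <- if (is(labeling, "StateLabeling")) labeling@labels
            else unique(lab)
  out <- do.call(rbind, lapply(unique(periods), function(p) {
    sel <- periods == p
    tab <- table(factor(lab[sel], levels = labels))
    data.frame(period = p, label = labels,
               proportion = as.numeric(tab) / sum(sel),
               minutes = as.numeric(tab), row.names = NULL)
  }))
  out
}

#' Mean bout durations per state and period
#'
#' A bout is a maximal run of bins decoded to the same label.  Bouts
#' spanning a day/night boundary are truncated at the boundary and each
#' fragment is counted in its own period, conserving per-period totals.
#' A label absent from a period yields NA (missing), not zero.
#'
#' @inheritParams stateProportions
#' @return data.frame with columns \code{period}, \code{label},
#'   \code{meanBoutMin}, \code{nBouts}.
#' @export
boutDurations <- function(seq, labeling, periods) {
  .stop_if(length(periods) != length(seq@states),
           "periods and decoded states must have equal length")
  lab <- .label_seq(seq, labeling)
  labels <- if (is(labeling, "StateLabeling")) labeling@labels
            else unique(lab)
  # cut runs at label changes and at period changes
  r <- rle(paste(lab, periods, sep = "\r"))
  parts <- do.call(rbind, strsplit(r$values, "\r", fixed = TRUE))
  bouts <- data.frame(label = parts[, 1L], period = parts[, 2L],
                      len = r$lengths)
  out <- expand.grid(period = unique(periods), label = labels,
                     stringsAsFactors = FALSE)
  out$meanBoutMin <- mapply(function(p, l) {
    x <- bouts$len[bouts$period == p & bouts$label == l]
    if (length(x)) mean(x) else NA_real_
  }, out$period, out$label)
  out$nBouts <- mapply(function(p, l)
    sum(bouts$period == p & bouts$label == l), out$period, out$label)
  out
}

#' Smoothed state-probability time courses
#'
#' Centered moving average of the posterior state probabilities with a
#' 61-bin window (a centered 60-minute span), shrinking symmetrically at
#' the edges.  Label curves sum to 1 at every time point.
#'
#' @param posteriors T x K posterior matrix (or a [StateSequence-class]).
#' @param labeling optional [StateLabeling-class] for column names.
#' @param windowBins odd window length in bins (default 61).
#' @return T x K matrix of smoothed probabilities.
#' @export
smoothedStateProbabilities <- function(posteriors, labeling = NULL,
                                       windowBins = 61L) {
  if (is(posteriors, "StateSequence"))
    posteriors <- posteriors@posteriors
  .stop_if(windowBins %% 2L != 1L, "windowBins must be odd (centered)")
  Tn <- nrow(posteriors)
  .stop_if(windowBins > Tn, "window longer than the trace")
  half <- (windowBins - 1L) %/% 2L
  cs <- rbind(0, apply(posteriors, 2L, cumsum))
  lo <- pmax(seq_len(Tn) - half, 1L)
  hi <- pmin(seq_len(Tn) + half, Tn)
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  if (!is.null(labeling))
    colnames(sm) <- if (is(labeling, "StateLabeling")) labeling@labels
                    else as.character(labeling)
  sm
}

#' Compare deep-sleep (S2) time with conventionally defined sleep
#'
#' Per fish and period, hours decoded to S2 versus hours of zero-activity
#' bins (the conventional one-minute immobility definition), with Pearson
#' correlation and deviation from the identity line across fish.  Decoded
#' S2 typically sits slightly below conventional sleep: some zero-activity
#' bins are assigned to light sleep S1 by sequence context.
#'
#' @param seqs list of [StateSequence-class], one per fish.
#' @param labeling shared [StateLabeling-class], or list of labelings.
#' @param traces list of [ActivityTrace-class], aligned with \code{seqs}.
#' @param periodsList list of per-bin period label vectors.
#' @param sleepLabel which label counts as model sleep (default
#'   \code{"S2"}).
#' @return List with \code{perFish} (data.frame fish, period, s2Hours,
#'   conventionalHours) and \code{fit} (Pearson r, p, mean signed
#'   deviation from y = x; NULL for fewer than 3 points).
#' @export
compareConventionalSleep <- function(seqs, labeling, traces, periodsList,
                                     sleepLabel = "S2") {
  n <- length(seqs)
  labs <- if (is(labeling, "StateLabeling")) rep(list(labeling), n)
          else labeling
  per_fish <- do.call(rbind, lapply(seq_len(n), function(i) {
    lab <- .label_seq(seqs[[i]], labs[[i]])
    zero <- activityValues(traces[[i]]) == 0L
    periods <- periodsList[[i]]
    do.call(rbind, lapply(unique(periods), function(p) {
      sel <- periods == p
      data.frame(fish = fishId(traces[[i]]), period = p,
                 s2Hours = sum(lab[sel] == sleepLabel) / 60,
                 conventionalHours = sum(zero[sel]) / 60)
    }))
  }))
  fit <- if (n >= 3L)
    pearsonIdentityFit(per_fish$conventionalHours, per_fish$s2Hours)
  else NULL
  list(perFish = per_fish, fit = fit)
}

#' State assignment conditioned on activity value
#'
#' For each observed activity value, the fraction of bins decoded to each
#' label, overall and split by day/night.  Rows sum to 1.  The split
#' exposes the HMM's context sensitivity: the same activity value is
#' assigned to different states depending on the surrounding sequence.
#'
#' @inheritParams compareConventionalSleep
#' @return data.frame with columns \code{scope} (overall/day/night),
#'   \code{activity}, one column per label, and \code{n}.
#' @export
assignmentByActivity <- function(seqs, labeling, traces, periodsList) {
  n <- length(seqs)
  labs <- if (is(labeling, "StateLabeling")) rep(list(labeling), n)
          else labeling
  labels <- if (is(labeling, "StateLabeling")) labeling@labels
            else labs[[1L]]@labels
  lab <- unlist(lapply(seq_len(n), function(i)
    .label_seq(seqs[[i]], labs[[i]])))
  act <- unlist(lapply(traces, activityValues))
  per <- unlist(periodsList)
  one_scope <- function(scope, sel) {
    vals <- sort(unique(act[sel]))
    do.call(rbind, lapply(vals, function(v) {
      s <- sel & act == v
      tab <- table(factor(lab[s], levels = labels))
      row <- as.data.frame(as.list(as.numeric(tab) / sum(s)))
      names(row) <- labels
      cbind(data.frame(scope = scope, activity = v), row,
            data.frame(n = sum(s)))
    }))
  }
  rbind(one_scope("overall", rep(TRUE, length(act))),
        one_scope("day", per == "day"),
        one_scope("night", per == "night"))
}

#' Label-aligned average of fitted parameters across fish
#'
#' Aligns each fit's states by semantic label, then averages rates and
#' transition matrices entrywise; averaged transition rows are
#' re-normalized to sum to 1 (entrywise means of stochastic rows are
#' stochastic up to numeric drift).
#'
#' @param fits list of [FitResult-class] (or [HMMParams-class]).
#' @param labelings list of [StateLabeling-class], one per fit (computed
#'   via [labelStates()] when missing).
#' @return List with \code{lambdas} (named mean rates) and
#'   \code{transitions} (label-indexed mean matrix).
#' @export
averageParameters <- function(fits, labelings = NULL) {
  params <- lapply(fits, function(f)
    if (is(f, "FitResult")) f@params else f)
  if (is.null(labelings)) labelings <- lapply(params, labelStates)
  label_sets <- lapply(labelings, function(l) sort(l@labels))
  .stop_if(!all(vapply(label_sets, identical, logical(1),
                       label_sets[[1L]])),
           "fits have heterogeneous label sets")
  labels_ord <- labelings[[1L]]@labels[
    order(params[[1L]]@lambdas)]
  aligned <- lapply(seq_along(params), function(i) {
    perm <- match(labels_ord, labelings[[i]]@labels)
    list(lam = params[[i]]@lambdas[perm],
         A = params[[i]]@transitions[perm, perm, drop = FALSE])
  })
  lam <- Reduce(`+`, lapply(aligned, `[[`, "lam")) / length(aligned)
  A <- Reduce(`+`, lapply(aligned, `[[`, "A")) / length(aligned)
  A <- A / rowSums(A)
  dimnames(A) <- list(labels_ord, labels_ord)
  list(lambdas = stats::setNames(lam, labels_ord), transitions = A)
}
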