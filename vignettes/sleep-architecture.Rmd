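---
title: "Modeling zebrafish sleep architecture with Poisson hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling zebrafish sleep architecture with Poisson hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepHMM)
```

## The model

Larval zebrafish locomotor activity is recorded as *seconds of movement
per minute*: an integer $x_t \in \{0, \dots, 60\}$ per 1-min bin $t$,
typically over 48 h (2880 bins) of a 14:10 light:dark cycle.  sleepHMM
models such a series as a hidden Markov chain over $K$ behavioral
states.  State $k$ emits activity counts from a Poisson distribution
with mean $\lambda_k$ (s/min), and the chain moves between states with
a row-stochastic transition matrix $A$; the next state depends only on
the current one.  The marginal likelihood of a trace is computed by the
scaled forward recursion, parameters are estimated by Baum-Welch EM,
the most probable state path by Viterbi decoding, and the long-run
state occupancy by the dominant eigenvector of $A$.

Four states are the typical optimum for standard day/night recordings:
in ascending rate order they are labeled **S2** (deep sleep,
$\lambda \approx 0$), **S1** (light sleep, $\lambda \approx 1$), and
the wake states **W1** and **W2** ($\lambda \approx 4$ and $8$).  The
conventional behavioral definition of zebrafish sleep — any 1-min bin
with zero activity — corresponds closely but not exactly to S2: the
model assigns some zero-activity bins to S1 because of the surrounding
sequence context, which is why model-defined deep sleep sits slightly
below conventionally defined sleep.

The number of states is chosen by the Bayesian Information Criterion,
$\mathrm{BIC} = p\ln n - 2\ell$, minimized over $K = 2,\dots,6$.  The
free-parameter count is $p = (K-1) + K(K-1) + K = K^2 + K - 1$ for
Poisson emissions (initial distribution, transition rows, rates) and
$p = K^2 + 2K - 1$ with zero-inflated Poisson emissions.  BIC ties
break toward smaller $K$ (parsimony).

Under free-running constant darkness the highest-activity wake state
disappears and three states fit best; these are labeled S2, S1 and W
by the same rate ordering, cross-checked against the reference rates
by nearest match.  An ordering/nearest-reference conflict is recorded
as a warning rather than an error, because the original three-state
assignment also used circadian timing arguments that cannot be fully
automated from rates alone.

## Fitting protocol and its tunables

EM converges only locally, so every fit is repeated from random
initializations and the best log-likelihood wins (`fitMultistart()`).
The defaults, and why:

* **Restarts** — configurable; 1000 restarts reproduce the reference
  protocol for real recordings, while tests and simulation experiments
  default to 20, which is ample for well-separated synthetic rates.
* **Initialization** — rates start at $K$ interior quantiles of the
  pooled observations (pushed off zero) with lognormal jitter
  (sd 0.3); transition rows start near-diagonal (self-transition 0.8,
  rest uniform) with Dirichlet-like gamma jitter; the initial
  distribution starts uniform.  All jitter derives from the restart
  seed, so fits are bit-reproducible.
* **Convergence** — EM stops when the log-likelihood gain drops below
  `tol = 1e-4`, or after `maxIter = 500` iterations.  The reported
  log-likelihood is always evaluated at the returned parameters, so
  the per-iteration trail is non-decreasing by construction.
* **Rate floor** — $\lambda_k \ge 10^{-3}$ s/min.  Real deep sleep
  sits near 0.02 s/min, so the floor is far below the data scale; it
  only prevents degenerate zero-rate states.  A state that loses all
  posterior mass is floored and flagged.
* **Emission family** — plain Poisson by default; `emission = "zip"`
  adds a per-state zero-inflation weight $w_k$ as a robustness
  variant.  With $w_k = 0$ the ZIP likelihood equals the Poisson
  likelihood exactly.
* **Ties** — Viterbi ties break toward the lower state index, making
  decoded paths deterministic.

Seeds everywhere follow one convention: a single base seed is expanded
by a counter scheme (`deriveSeed`) into per-restart, per-fish and
per-sequence seeds, all below $2^{31}$, and multi-restart winners
record their seed.

## Sleep-architecture summaries

Decoded sequences are summarized per fish as day/night state
proportions, per-period mean bout durations, long-run occupancies, a
comparison with conventionally defined sleep (Pearson correlation and
deviation from the $y = x$ line), and activity-conditioned assignment
tables $P(\text{state} \mid x)$ split by day and night.  Two
conventions needed a decision the source protocol leaves open:

* **Bouts at period boundaries** — a bout spanning the day/night
  boundary is truncated there, with each fragment counted in its own
  period.  This conserves per-period totals exactly (proportions
  times period length always equal summed bout minutes).
* **Smoothing window** — state-probability time courses are smoothed
  with a centered 61-bin moving average (a "60-minute" span must be
  odd to be centered), shrinking symmetrically at the edges so label
  curves still sum to 1 at every time point.

## Arousal analysis

For stimulus experiments, bins are aligned so each stimulus falls at a
bin boundary; the state of the bin *ending* at the stimulus is the
fish's state.  A response is any movement within 2 s after the
stimulus.  The raw response fraction per state is corrected by a
baseline: the same 2-s detector applied at the start of the bin
beginning 120 s before the stimulus, conditioned on *that* bin's own
decoded state (the baseline estimates what a fish in a given state
does without a stimulus, so the conditioning state must be the
baseline bin's).  The window placement within the baseline bin is
ambiguous in the source protocol; the first 2 s mirror the
post-stimulus alignment and is used here.  Single-night recordings are
too short for reliable per-fish fits, so arousal analyses default to
one pooled (concatenated) 4-state fit across fish, and fish whose
decoded path misses any state are excluded before computing fractions.

## Group statistics

Differences in fitted parameters between cohorts are tested with a
two-sided permutation test on the absolute difference of group means:
exact enumeration when the number of group assignments is at most
20,000, otherwise Monte Carlo with $+1$ smoothing so $p > 0$.  The
source protocol couples "bootstrap sampling" with a permutation test
without further detail; here the p-value comes from the permutation
test alone, and the bootstrap (2000 resamples) only reports a
percentile confidence interval on the group difference.  Family-wise
Bonferroni factors are 4 for occupancies and rates and 16 for the
transition probabilities of a 4-state model.  State-proportion and
response-fraction contrasts use Welch t-tests (the unequal-variance
form, since only "t-tests" is specified) with Benjamini-Hochberg
correction, optionally on arcsine-square-root-transformed fractions;
day/night pairings use the Wilcoxon signed-rank test, exact up to 25
non-zero differences.

## The synthetic-cohort generator

`generateCohort()` stands in for real recordings.  Per fish it draws a
hidden path from a *day* transition matrix during light bins and a
*night* matrix during dark bins (switching at the boundaries), emits
Poisson counts from per-fish rates jittered by a lognormal factor
(sd 0.1), and clips at 60 s/min.  The circadian structure therefore
lives entirely in the transitions — state rates are
period-independent, matching the single homogeneous HMM used for
fitting, whose BIC optimum remains $K = 4$ on such data.

The base rates are the group-level wild-type values (0.02, 1.18, 4.07,
7.49 s/min).  The day and night matrices are package constants, not
fitted values: the night matrix puts about 80% of its long-run mass on
S2+S1 and the day matrix about 75% on W1+W2, with self-transitions at
or above 0.85, chosen once so that simulated proportion and bout
patterns show the qualitative circadian architecture of real
recordings.  Manipulation presets (`sleepPreset()`) perturb these
matrices *directionally* — e.g. the melatonin-deficiency preset moves
night mass from S2 to S1, the serotonin-agonist preset the reverse,
the constant-dark preset drops to a three-state generator under a
subjective schedule — because the source material quantifies rates and
a few transition probabilities but not full effect sizes; presets are
directional emulations, not quantitative reproductions.

Sleep deprivation is modeled phenomenologically: night 2's first 6 h
follow the day matrix (light-forced wakefulness), and during the final
4 h the deep-sleep self-transition is incremented by a rebound boost
(default 0.05) with the remaining off-diagonal mass rescaled, a
stand-in for homeostatic pressure rather than a mechanism.  Arousal
experiments emit 1-Hz raw traces whose per-minute totals follow the
hidden path, and inject a response (movement within 2 s) after each
stimulus with a per-state probability, independent of spontaneous
activity.

What the generator does *not* emulate — and therefore what passing
tests cannot certify about real data: gradual circadian transitions
around lights-on/off (the matrices switch instantaneously), dependence
of rates on time of day, between-batch variability beyond per-fish
rate jitter, habituation to repeated stimuli, and any longer-range
temporal dependence that violates the Markov assumption.

## Surrogate-data experiments and problem sizes

Two validation experiments mirror the reference analysis.
`stateNumberRecoveryExperiment()` samples surrogate sequences from a
4-state model built on the printed wild-type rates with a strongly
self-persistent transition matrix (`wtReferenceParams()`: reported
off-diagonal entries where available, 0.05 elsewhere, diagonals
absorbing the remainder), refits each over $K = 2$–$6$, and reports
how often BIC recovers $K = 4$; at 2880 bins this is the reference
94% result, run here at 50 sequences with 20 restarts.
`lengthSufficiencyExperiment()` shows parameter-recovery error
shrinking from 10 h to 72 h of data, supporting 48 h as sufficient.
The package's own test suite exercises these at the sizes above;
smaller unit tests use 6–10 sequences and 600–4320 bins, and preset
contrasts use 10 fish per arm at 48 h with 5 restarts — sizes chosen
to make directional effects statistically unambiguous at simulation
cost a laptop handles comfortably.

## Known limitations

The Markov and Poisson assumptions are conveniences: real behavior has
longer temporal dependencies, and bounded counts are not truly
Poisson (sampling clips at 60 s/min and counts clip events).  Semantic
labels derive from rate ordering plus a reference-rate cross-check and
can mislabel fits whose rates fall far from the reference pattern —
such fits carry warnings and deserve manual review.  The
stationary-distribution occupancy assumes an irreducible fitted chain;
reducible or periodic fits fall back to empirical path frequencies
when a decoded path is supplied.  Finally, all quantitative claims in
this package's tests concern its own generator; agreement with real
recordings is qualitative by design.
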