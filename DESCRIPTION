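Package: sleepHMM
Title: Hidden Markov Segmentation of Sleep and Wake Sub-States from
    Larval Zebrafish Locomotor Activity
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments 1-minute binned locomotor activity of larval
    zebrafish into behaviorally defined sleep and wake sub-states
    (deep sleep S2, light sleep S1, and wake states W1/W2) using
    Poisson hidden Markov models fitted by multi-restart Baum-Welch
    EM, with BIC selection of the number of hidden states.  Provides
    state-resolved sleep-architecture summaries (occupancies, day and
    night proportions, bout durations, smoothed state-probability
    time courses, comparison with the conventional one-minute
    immobility definition of sleep), stimulus-aligned arousability
    analysis with baseline correction, sleep-deprivation rebound
    protocols, permutation and bootstrap group statistics with
    Bonferroni and Benjamini-Hochberg correction, and a circadian
    synthetic-cohort generator with presets emulating genetic and
    pharmacological manipulations of melatonin, serotonin and
    noradrenaline signaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'activity.R'
    'utils.R'
    'hmm.R'
    'selection.R'
    'arousal.R'
    'io.R'
    'stats.R'
    'state-analysis.R'
    'synthetic.R'
    'pipeline.R'
    'sleepHMM-package.R'
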