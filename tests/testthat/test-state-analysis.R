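test_that("state labeling follows ascending rate with reference
           cross-check", {
  # group-level rates in scrambled state order
  p <- HMMParams(rep(0.25, 4), matrix(0.25, 4, 4),
                 c(4.07, 0.02, 7.49, 1.18))
  lab <- labelStates(p)
  expect_equal(stateLabels(lab), c("W1", "S2", "W2", "S1"))
  expect_length(lab@warnings, 0)

  # 3-state free-running fit
  p3 <- HMMParams(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                  c(0.03, 1.2, 4.0))
  expect_equal(stateLabels(labelStates(p3)), c("S2", "S1", "W"))

  # K = 2 falls back to generic labels with a warning
  p2 <- HMMParams(c(0.5, 0.5), matrix(0.5, 2, 2), c(0.5, 5))
  expect_warning(lab2 <- labelStates(p2), "generic")
  expect_equal(stateLabels(lab2), c("sleepLike", "wakeLike"))

  # tied rates are an error
  ptie <- HMMParams(rep(0.25, 4), matrix(0.25, 4, 4),
                    c(1, 1 + 1e-9, 4, 8))
  expect_error(labelStates(ptie), "tie")

  # an implausible rate pattern triggers the nearest-match warning
  podd <- HMMParams(rep(0.25, 4), matrix(0.25, 4, 4),
                    c(0.02, 0.05, 0.08, 7.49))
  labodd <- labelStates(podd)
  expect_gt(length(labodd@warnings), 0)
})

test_that("occupancy maps the stationary distribution through labels", {
  A <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  p <- HMMParams(c(0.5, 0.5), A, c(0.5, 5))
  occ <- suppressWarnings(occupancy(p))
  expect_equal(unname(occ), c(1 / 3, 2 / 3))
  expect_equal(names(occ), c("sleepLike", "wakeLike"))
  expect_equal(sum(occ), 1)

  # uniform rows -> equal occupancies
  p4 <- HMMParams(rep(0.25, 4), matrix(0.25, 4, 4),
                  c(0.02, 1.18, 4.07, 7.49))
  expect_equal(unname(occupancy(p4)), rep(0.25, 4))

  # occupancy close to hidden-path frequencies of a long simulation
  gen <- wtReferenceParams()
  sim <- sampleHMM(gen, 50000, seed = 13)
  occ <- occupancy(gen)
  freq <- tabulate(sim$path, 4) / 50000
  for (k in 1:4) {
    se <- sqrt(occ[k] * (1 - occ[k]) / 50000)
    # correlated samples: allow a generous multiple of the iid SE
    expect_lt(abs(freq[k] - occ[k]), 12 * se)
  }
})

mk_seq <- function(states, K) {
  post <- matrix(0, length(states), K)
  post[cbind(seq_along(states), states)] <- 1
  new("StateSequence", states = as.integer(states), posteriors = post,
      labeling = character(0))
}

lab4 <- labelStates(HMMParams(rep(0.25, 4), matrix(0.25, 4, 4),
                              c(0.02, 1.18, 4.07, 7.49)))

test_that("state proportions partition each period", {
  # all-S2 night, all-W1 day toy path
  states <- c(rep(3L, 5), rep(1L, 5))  # W1 then S2 (index = label order)
  periods <- c(rep("day", 5), rep("night", 5))
  props <- stateProportions(mk_seq(states, 4), lab4, periods)
  expect_equal(props$proportion[props$period == "night" &
                                props$label == "S2"], 1)
  expect_equal(props$proportion[props$period == "day" &
                                props$label == "W1"], 1)
  # fractions sum to 1 per period; minutes consistent
  for (p in c("day", "night")) {
    expect_equal(sum(props$proportion[props$period == p]), 1)
    expect_equal(sum(props$minutes[props$period == p]), 5)
  }
  expect_error(stateProportions(mk_seq(states, 4), lab4, periods[-1]),
               "length")
})

test_that("bout durations truncate at period boundaries", {
  # S2,S2,S1,S2 in one period: S2 bouts {2, 1}, mean 1.5
  b <- boutDurations(mk_seq(c(1L, 1L, 2L, 1L), 4), lab4,
                     rep("night", 4))
  expect_equal(b$meanBoutMin[b$label == "S2" & b$period == "night"], 1.5)
  expect_equal(b$nBouts[b$label == "S2" & b$period == "night"], 2L)

  # a 5-bin run spanning the boundary: day fragment 3, night fragment 2
  b2 <- boutDurations(mk_seq(rep(4L, 5), 4), lab4,
                      c("day", "day", "day", "night", "night"))
  expect_equal(b2$meanBoutMin[b2$label == "W2" & b2$period == "day"], 3)
  expect_equal(b2$meanBoutMin[b2$label == "W2" & b2$period == "night"], 2)

  # absent label yields NA, not zero
  expect_true(is.na(b2$meanBoutMin[b2$label == "S2" &
                                   b2$period == "day"]))
})

test_that("smoothed probabilities conserve mass and fixed points", {
  # constant posteriors unchanged
  post <- matrix(rep(c(0.2, 0.8), each = 200), 200, 2)
  sm <- smoothedStateProbabilities(post, windowBins = 61)
  expect_equal(sm, post)

  # unit impulse: mass preserved, spread over the window
  post2 <- cbind(rep(0, 301), rep(1, 301))
  post2[151, ] <- c(1, 0)
  sm2 <- smoothedStateProbabilities(post2, windowBins = 61)
  expect_equal(sum(sm2[, 1]), 1, tolerance = 1e-9)  # away from edges
  expect_equal(max(sm2[, 1]), 1 / 61, tolerance = 1e-12)

  # rows sum to 1 everywhere (edges included)
  set.seed(4)
  raw <- matrix(rgamma(300 * 3, 1), 300, 3)
  post3 <- raw / rowSums(raw)
  sm3 <- smoothedStateProbabilities(post3, windowBins = 61)
  expect_true(all(abs(rowSums(sm3) - 1) < 1e-9))

  expect_error(smoothedStateProbabilities(post3, windowBins = 60),
               "odd")
  expect_error(smoothedStateProbabilities(post3[1:30, ],
                                          windowBins = 61), "longer")
})

test_that("conventional-sleep comparison recovers exact agreement", {
  # three fish whose S2 bins are exactly their zero-activity bins
  traces <- list()
  seqs <- list()
  periods <- list()
  for (i in 1:3) {
    set.seed(i)
    states <- sample(1:4, 200, replace = TRUE)
    act <- ifelse(states == 1L, 0L, states)  # zero iff S2
    traces[[i]] <- ActivityTrace(paste0("f", i), act)
    seqs[[i]] <- mk_seq(states, 4)
    periods[[i]] <- rep(c("day", "night"), each = 100)
  }
  cmp <- compareConventionalSleep(seqs, lab4, traces, periods)
  expect_equal(cmp$perFish$s2Hours, cmp$perFish$conventionalHours)
  expect_equal(cmp$fit$r, 1, tolerance = 1e-12)
  expect_equal(cmp$fit$meanDeviation, 0)

  # single fish: correlation omitted
  cmp1 <- compareConventionalSleep(seqs[1], lab4, traces[1], periods[1])
  expect_null(cmp1$fit)
})

test_that("activity-conditioned assignment rows are distributions", {
  set.seed(9)
  states <- sample(1:4, 400, replace = TRUE)
  act <- pmin(rpois(400, c(0.02, 1.18, 4.07, 7.49)[states]), 60L)
  tr <- ActivityTrace("f", act)
  seq <- mk_seq(states, 4)
  periods <- rep(c("day", "night"), each = 200)
  tab <- assignmentByActivity(list(seq), lab4, list(tr), list(periods))
  lab_cols <- c("S2", "S1", "W1", "W2")
  expect_true(all(abs(rowSums(tab[, lab_cols]) - 1) < 1e-9))

  # one-state model: unit rows
  seq1 <- mk_seq(rep(1L, 100), 4)
  tr1 <- ActivityTrace("g", pmin(rpois(100, 1), 60L))
  tab1 <- assignmentByActivity(list(seq1), lab4, list(tr1),
                               list(rep("day", 100)))
  expect_true(all(tab1$S2 == 1))
})

test_that("parameter averaging aligns labels and renormalizes", {
  p1 <- HMMParams(rep(0.25, 4), transitionMatrix(wtReferenceParams()),
                  c(0.02, 1.18, 4.07, 7.49))
  # same model with states listed in reverse order
  perm <- 4:1
  p2 <- HMMParams(rep(0.25, 4),
                  transitionMatrix(p1)[perm, perm],
                  stateRates(p1)[perm])
  avg <- averageParameters(list(p1, p2))
  expect_equal(unname(avg$lambdas), c(0.02, 1.18, 4.07, 7.49))
  expect_equal(unname(avg$transitions),
               unname(transitionMatrix(p1)), tolerance = 1e-12)
  expect_equal(unname(rowSums(avg$transitions)), rep(1, 4))

  # entrywise mean before renormalization
  q <- HMMParams(rep(0.25, 4),
                 0.5 * transitionMatrix(p1) + 0.125, c(0.04, 1.3, 4, 8))
  avg2 <- averageParameters(list(p1, q))
  expect_equal(unname(avg2$transitions),
               unname((transitionMatrix(p1) +
                       transitionMatrix(q)) / 2), tolerance = 1e-12)

  # heterogeneous label sets are rejected
  p3 <- HMMParams(rep(1 / 3, 3), matrix(1 / 3, 3, 3), c(0.02, 1.2, 4))
  expect_error(averageParameters(list(p1, p3)), "heterogeneous")
})
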