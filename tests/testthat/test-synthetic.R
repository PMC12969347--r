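test_that("cohort generation is deterministic and circadian", {
  spec <- sleepPreset("wt")
  a <- generateCohort(spec, nFish = 3, duration = 720L, seed = 9)
  b <- generateCohort(spec, nFish = 3, duration = 720L, seed = 9)
  expect_identical(lapply(cohortTraces(a$cohort), activityValues),
                   lapply(cohortTraces(b$cohort), activityValues))
  expect_identical(a$truth[[2]]$path, b$truth[[2]]$path)

  # 48-h wild-type cohort: day activity exceeds night activity, and the
  # activity histogram has its mode at zero with a heavy right tail
  sim <- generateCohort(spec, nFish = 10, duration = 2880L, seed = 4)
  act <- unlist(lapply(cohortTraces(sim$cohort), activityValues))
  per <- rep(sim$periods, 10)
  expect_gt(mean(act[per == "day"]), mean(act[per == "night"]))
  tab <- table(act)
  expect_equal(names(which.max(tab)), "0")
  skw <- mean((act - mean(act))^3) / sd(act)^3
  expect_gt(skw, 0)

  # generated traces satisfy the trace invariants
  for (tr in cohortTraces(sim$cohort)) {
    v <- activityValues(tr)
    expect_true(all(v >= 0L & v <= 60L))
    expect_true(is.integer(v))
  }
})

test_that("hidden-path transition frequencies match the generating
           matrices within each lighting period", {
  spec <- sleepPreset("wt")
  spec@jitterSd <- 0
  # long recording: many day and night bins
  n_days <- 35
  sched <- defaultSchedule(days = n_days)
  spec@schedule <- sched
  sim <- generateCohort(spec, nFish = 2, duration = n_days * 1440L,
                        seed = 77)
  per <- sim$periods
  for (f in 1:2) {
    path <- sim$truth[[f]]$path
    from <- path[-length(path)]
    to <- path[-1]
    per_from <- per[-length(path)]
    for (pd in c("day", "night")) {
      A <- if (pd == "day") spec@dayTransitions else spec@nightTransitions
      for (i in 1:4) {
        sel <- per_from == pd & from == i
        n_i <- sum(sel)
        if (n_i < 200) next
        for (j in 1:4) {
          phat <- sum(sel & to == j) / n_i
          se <- sqrt(A[i, j] * (1 - A[i, j]) / n_i)
          expect_lt(abs(phat - A[i, j]), 3.5 * se + 1e-12)
        }
      }
    }
  }
})

test_that("sleep deprivation forces wake then boosts deep-sleep
           rebound", {
  spec <- sleepPreset("wt")
  spec@jitterSd <- 0

  # positive boost: S2 proportion in the rebound window exceeds the
  # matched clock window of night 1, S1 is lower
  sim <- generateSleepDeprivation(spec, nFish = 30, seed = 12)
  rb <- sim$reboundWindow
  n1 <- rb - 1440L  # same clock hours on night 1
  s2_rb <- mean(vapply(sim$truth, function(t)
    mean(t$labels[rb] == "S2"), numeric(1)))
  s2_n1 <- mean(vapply(sim$truth, function(t)
    mean(t$labels[n1] == "S2"), numeric(1)))
  s1_rb <- mean(vapply(sim$truth, function(t)
    mean(t$labels[rb] == "S1"), numeric(1)))
  s1_n1 <- mean(vapply(sim$truth, function(t)
    mean(t$labels[n1] == "S1"), numeric(1)))
  expect_gt(s2_rb, s2_n1)
  expect_lt(s1_rb, s1_n1)

  # lights-on deprivation window is wake-dominated
  dep <- (38L * 60L + 1L):(44L * 60L)
  w_dep <- mean(vapply(sim$truth, function(t)
    mean(t$labels[dep] %in% c("W1", "W2")), numeric(1)))
  expect_gt(w_dep, 0.5)

  # zero boost: rebound window statistically matches night 1
  spec0 <- spec
  spec0@reboundBoost <- 0
  sim0 <- generateSleepDeprivation(spec0, nFish = 50, seed = 13)
  d <- vapply(sim0$truth, function(t)
    mean(t$labels[rb] == "S2") - mean(t$labels[n1] == "S2"), numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("arousal generator aligns stimuli and encodes response
           probabilities", {
  spec <- sleepPreset("wt")
  sim <- generateArousalExperiment(spec, nFish = 4, nStimuli = 30,
                                   seed = 3)
  start <- sim$raws[[1]]@startClock
  offs <- as.numeric(sim$protocol@times) - as.numeric(start)
  expect_true(all(offs %% 60 == 0))
  expect_equal(diff(offs), rep(300, 29))

  # with zero response probabilities the injected-response channel is
  # silent: corrected fractions are near zero
  spec0 <- spec
  spec0@responseProbs <- rep(0, 4)
  sim0 <- generateArousalExperiment(spec0, nFish = 10, nStimuli = 100,
                                    seed = 6)
  gp <- HMMParams(stationaryDistribution(spec0@nightTransitions),
                  spec0@nightTransitions, spec0@lambdas)
  lab <- labelStates(gp)
  traces <- lapply(sim0$raws, binActivity)
  seqs <- lapply(traces, function(tr) decodeStates(gp, tr, lab))
  res <- responseFractions(sim0$raws, seqs, lab, sim0$protocol)
  ok <- !is.na(res$corrected) & res$n >= 80
  expect_gte(sum(ok), 2)
  expect_true(all(abs(res$corrected[ok]) < 0.15))
})

test_that("presets cover the documented manipulations", {
  expect_error(sleepPreset("nope"), "available")
  wt <- sleepPreset("wt")
  night_occ <- function(s) {
    occ <- stationaryDistribution(s@nightTransitions)
    names(occ) <- s@labels
    occ
  }
  day_occ <- function(s) {
    occ <- stationaryDistribution(s@dayTransitions)
    names(occ) <- s@labels
    occ
  }
  # generator-level directional effects
  aan <- sleepPreset("aanat2_like")
  expect_lt(night_occ(aan)["S2"], night_occ(wt)["S2"])
  expect_gt(night_occ(aan)["S1"], night_occ(wt)["S1"])
  qui <- sleepPreset("quipazine_like")
  expect_gt(night_occ(qui)["S2"], night_occ(wt)["S2"])
  expect_lt(night_occ(qui)["S1"], night_occ(wt)["S1"])
  mel <- sleepPreset("melatonin_treated")
  expect_lt(day_occ(mel)["W2"], day_occ(wt)["W2"])
  dbh <- sleepPreset("dbh_like")
  expect_gt(night_occ(dbh)["S2"], night_occ(wt)["S2"])
  expect_gt(day_occ(dbh)["S2"], day_occ(wt)["S2"])
  cd <- sleepPreset("constant_dark")
  expect_equal(cd@labels, c("S2", "S1", "W"))
  expect_true(all(scheduleIntervals(cd@schedule)$condition %in%
                  c("subjective_day", "subjective_night")))
})

test_that("spec YAML config round-trips", {
  spec <- sleepPreset("wt")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSpecConfig(spec, path)
  back <- readSpecConfig(path)
  expect_equal(back@lambdas, spec@lambdas)
  expect_equal(unname(back@nightTransitions),
               unname(spec@nightTransitions), tolerance = 1e-9)
  expect_equal(back@responseProbs, spec@responseProbs)
  expect_equal(back@labels, spec@labels)
})
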