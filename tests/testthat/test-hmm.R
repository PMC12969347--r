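test_that("emission log-pmf matches direct evaluation", {
  expect_equal(emissionLogPmf(0, 1), log(exp(-1)))
  expect_equal(emissionLogPmf(0, 1, w = 0.5), log(0.5 + 0.5 * exp(-1)))
  # direct factorial evaluation
  expect_equal(emissionLogPmf(3, 4.07),
               log(exp(-4.07) * 4.07^3 / factorial(3)))
  # ZIP with w = 0 reproduces plain Poisson exactly
  x <- 0:10
  expect_equal(emissionLogPmf(x, 2.5, w = 0), emissionLogPmf(x, 2.5))
  expect_error(emissionLogPmf(-1, 1), "non-negative")
})

test_that("log-likelihood matches closed forms and enumeration", {
  # K = 1, lambda = 1, obs (0, 1): ln e^-1 + ln e^-1 = -2
  p1 <- HMMParams(1, matrix(1), 1)
  expect_equal(hmmLogLik(p1, c(0L, 1L)), -2)

  # brute-force path enumeration, K = 2, T = 6
  for (seed in 1:5) {
    p <- rand_hmm(2, seed)
    obs <- withr::with_seed(seed + 100, as.integer(rpois(6, 3)))
    expect_equal(hmmLogLik(p, obs),
                 brute_loglik(initialProbs(p), transitionMatrix(p),
                              stateRates(p), obs),
                 tolerance = 1e-10)
  }

  # absorbing state: pi = (1, 0), A keeps state 1 -> product of
  # state-1 emissions
  pA <- HMMParams(c(1, 0), rbind(c(1, 0), c(0.5, 0.5)), c(2, 7))
  obs <- c(1L, 3L, 0L)
  expect_equal(hmmLogLik(pA, obs), sum(dpois(obs, 2, log = TRUE)))

  # multi-sequence input sums per-sequence log-likelihoods
  p <- rand_hmm(2, 3)
  expect_equal(hmmLogLik(p, list(c(0L, 1L), c(2L, 0L))),
               hmmLogLik(p, c(0L, 1L)) + hmmLogLik(p, c(2L, 0L)))
})

test_that("posteriors match enumeration and limiting cases", {
  p1 <- HMMParams(1, matrix(1), 2)
  expect_equal(statePosteriors(p1, c(0L, 3L, 1L)), matrix(1, 3, 1))

  for (seed in 1:5) {
    p <- rand_hmm(2, seed + 10)
    obs <- withr::with_seed(seed, as.integer(rpois(6, 2)))
    expect_equal(statePosteriors(p, obs),
                 brute_posteriors(initialProbs(p), transitionMatrix(p),
                                  stateRates(p), obs),
                 tolerance = 1e-10)
  }

  # widely separated rates: an observed 0 pins the low state
  p <- HMMParams(c(0.5, 0.5), matrix(0.5, 2, 2), c(0.01, 50))
  post <- statePosteriors(p, 0L)
  expect_gt(post[1, 1], 0.999)
})

test_that("Viterbi matches enumeration and forced constructions", {
  p1 <- HMMParams(1, matrix(1), 2)
  expect_equal(viterbiPath(p1, c(0L, 3L)), c(1L, 1L))

  checked <- 0
  for (seed in 1:8) {
    p <- rand_hmm(3, seed + 20)
    obs <- withr::with_seed(seed, as.integer(rpois(6, 4)))
    truth <- brute_viterbi(initialProbs(p), transitionMatrix(p),
                           stateRates(p), obs)
    if (is.null(truth)) next  # near-tie: skip ambiguous instance
    expect_equal(viterbiPath(p, obs), truth)
    checked <- checked + 1
  }
  expect_gte(checked, 5)

  # near-identity transitions, well-separated rates: the path follows
  # the observation-nearest rate
  p <- HMMParams(c(1, 1, 1) / 3,
                 diag(3) * 0.97 + 0.01, c(0.1, 5, 20))
  obs <- c(0L, 0L, 5L, 5L, 20L, 21L)
  expect_equal(viterbiPath(p, obs), c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("forward, posterior and Viterbi agree with enumeration on
           random small instances (K <= 3, T <= 8)", {
  n_vit <- 0
  for (seed in 1:12) {
    K <- (seed %% 3) + 1
    T <- 4 + (seed %% 5)
    p <- rand_hmm(K, seed + 300)
    obs <- withr::with_seed(seed + 400, as.integer(rpois(T, 3)))
    pi <- initialProbs(p); A <- transitionMatrix(p); lam <- stateRates(p)
    expect_equal(hmmLogLik(p, obs), brute_loglik(pi, A, lam, obs),
                 tolerance = 1e-10)
    expect_equal(statePosteriors(p, obs),
                 brute_posteriors(pi, A, lam, obs), tolerance = 1e-10)
    vt <- brute_viterbi(pi, A, lam, obs)
    if (!is.null(vt)) {
      expect_equal(viterbiPath(p, obs), vt)
      n_vit <- n_vit + 1
    }
  }
  expect_gte(n_vit, 8)
})

test_that("EM reduces to the Poisson MLE at K = 1 and is monotone", {
  obs <- withr::with_seed(5, as.integer(rpois(400, 3.7)))
  fit <- fitEM(obs, 1)
  expect_equal(stateRates(fit)[1], mean(obs), tolerance = 1e-8)

  # log-likelihood trail non-decreasing on random instances
  for (seed in 1:20) {
    gen <- rand_hmm(2 + seed %% 2, seed + 600)
    sim <- sampleHMM(gen, 300, seed = seed)
    fit <- suppressWarnings(fitEM(sim$trace, hmmK(gen), initSeed = seed))
    expect_true(all(diff(fit@trail) > -1e-8))
  }
})

test_that("EM recovers generating rates within 3 standard errors", {
  gen <- HMMParams(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                   c(0.5, 6))
  sim <- sampleHMM(gen, 5000, seed = 99)
  fit <- fitMultistart(sim$trace, 2, nRestarts = 5, baseSeed = 2)
  lam <- sort(stateRates(fit))
  occ <- stationaryDistribution(gen)
  se <- sqrt(stateRates(gen) / (5000 * occ))
  expect_lt(abs(lam[1] - 0.5), 3 * se[1])
  expect_lt(abs(lam[2] - 6), 3 * se[2])
})

test_that("ZIP emission with w = 0 gives the Poisson likelihood", {
  p <- rand_hmm(2, 7)
  pz <- HMMParams(initialProbs(p), transitionMatrix(p), stateRates(p),
                  zeroWeights = c(0, 0))
  obs <- withr::with_seed(8, as.integer(rpois(50, 2)))
  expect_equal(hmmLogLik(pz, obs), hmmLogLik(p, obs), tolerance = 1e-12)
})

test_that("ZIP EM fits inflate zeros rather than rates", {
  # one-state data with extra zeros: ZIP separates spike from rate
  withr::with_seed(21, {
    x <- rpois(2000, 4)
    x[runif(2000) < 0.3] <- 0L
  })
  fit <- fitEM(as.integer(x), 1, emission = "zip")
  expect_equal(stateRates(fit)[1], 4, tolerance = 0.3)
  expect_equal(zeroWeights(fit@params)[1], 0.3, tolerance = 0.12)
})

test_that("sampling is reproducible and respects the generator", {
  gen <- wtReferenceParams()
  a <- sampleHMM(gen, 500, seed = 42)
  b <- sampleHMM(gen, 500, seed = 42)
  expect_identical(activityValues(a$trace), activityValues(b$trace))
  expect_identical(a$path, b$path)

  # absorbing construction: constant hidden path
  pA <- HMMParams(c(1, 0), diag(2), c(1, 5))
  expect_true(all(sampleHMM(pA, 200, seed = 1)$path == 1L))

  # floored near-zero rate: almost all zero observations
  p0 <- HMMParams(1, matrix(1), 1e-3)
  expect_gt(mean(activityValues(sampleHMM(p0, 500, seed = 2)$trace) == 0),
            0.99)

  # empirical transition frequencies within 3 sigma of A at T = 100000
  sim <- sampleHMM(gen, 100000, seed = 7)
  A <- transitionMatrix(gen)
  from <- sim$path[-length(sim$path)]
  to <- sim$path[-1]
  for (i in 1:4) {
    n_i <- sum(from == i)
    for (j in 1:4) {
      phat <- sum(from == i & to == j) / n_i
      se <- sqrt(A[i, j] * (1 - A[i, j]) / n_i)
      expect_lt(abs(phat - A[i, j]), 3 * se + 1e-12)
    }
  }
})

test_that("stationary distribution solves the balance equations", {
  expect_equal(stationaryDistribution(rbind(c(0.9, 0.1), c(0.1, 0.9))),
               c(0.5, 0.5))
  expect_equal(stationaryDistribution(rbind(c(0.5, 0.5),
                                            c(0.25, 0.75))),
               c(1 / 3, 2 / 3))
  # random 4-state chain vs long-run power iteration
  set.seed(31)
  A <- matrix(rgamma(16, 1) + 0.05, 4, 4)
  A <- A / rowSums(A)
  v <- rep(0.25, 4)
  for (i in 1:10000) v <- as.vector(v %*% A)
  expect_equal(stationaryDistribution(A), v, tolerance = 1e-8)

  # reducible chain: error without fallback, empirical with it
  R <- rbind(c(1, 0), c(0, 1))
  expect_error(stationaryDistribution(R), "fallback")
  expect_equal(stationaryDistribution(R, fallbackStates = c(1, 1, 2, 2)),
               c(0.5, 0.5))
  expect_error(stationaryDistribution(rbind(c(0.7, 0.7), c(0.2, 0.8))),
               "stochastic")
})

test_that("params JSON round-trip is exact", {
  p <- HMMParams(c(0.3, 0.7), rbind(c(0.123456789012, 0.876543210988),
                                    c(0.5, 0.5)),
                 c(0.02, 7.49), zeroWeights = c(0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  writeParams(p, path)
  q <- readParams(path)
  expect_equal(unname(transitionMatrix(q)), unname(transitionMatrix(p)),
               tolerance = 1e-13)
  expect_equal(zeroWeights(q), zeroWeights(p), tolerance = 1e-13)
})
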