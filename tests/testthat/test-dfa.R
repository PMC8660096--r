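test_that("signal profile is the mean-removed cumulative sum", {
  expect_equal(signalProfile(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(signalProfile(c(1, -1, 1, -1)), c(1, 0, 1, 0))
  set.seed(1)
  for (i in 1:5) {
    p <- signalProfile(rnorm(100))
    expect_equal(p[length(p)], 0)  # algebraic identity
  }
})

test_that("window lengths are log-equidistant integer sample counts", {
  taus <- windowLengths(1, 15, 15, 250)
  expect_identical(taus[1], 250L)
  expect_identical(taus[length(taus)], 3750L)
  ratios <- taus[-1] / taus[-length(taus)]
  expect_lt(diff(range(ratios)), 0.05)
  # delta/theta convention starts at 2 s
  expect_equal(bandMinTauS("delta"), 2)
  expect_equal(bandMinTauS("theta"), 2)
  expect_equal(bandMinTauS("alpha"), 1)
  expect_equal(bandMinTauS("high-gamma"), 1)
  expect_identical(windowLengths(2, 15, 15, 250)[1], 500L)
  expect_error(windowLengths(1, 15, 15, 250, n = 5000), "at least twice")
  expect_error(windowLengths(1, 15, 5, 250), "at least 6")
})

test_that("fluctuation function matches a literal brute-force oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(120:400, 1)
    tau <- sample(10:floor(n / 2), 1)
    prof <- signalProfile(rnorm(n))
    expect_equal(fluctuationFunction(prof, tau),
                 naiveFluctuation(prof, tau), tolerance = 1e-12)
  }
})

test_that("fluctuation of a linear profile is zero and F is non-negative", {
  lin <- 0.3 * (1:400) + 2
  expect_equal(fluctuationFunction(lin, 50), 0)
  set.seed(2)
  expect_gte(fluctuationFunction(signalProfile(rnorm(400)), 40), 0)
  expect_error(fluctuationFunction(rnorm(100), 80), "fewer than 2 windows")
})

test_that("DFA recovers the known exponents of reference processes", {
  # uncorrelated noise: alpha ~ 0.5
  aWhite <- mean(vapply(1:10, function(s)
    dfaAlpha(fitDFA(simulateFGN(2^13, 0.5, seed = s), fs = 250)),
    numeric(1)))
  expect_lt(abs(aWhite - 0.5), 0.05)
  # persistent fGn: alpha ~ H
  a8 <- mean(vapply(1:10, function(s)
    dfaAlpha(fitDFA(simulateFGN(2^13, 0.8, seed = 100 + s), fs = 250)),
    numeric(1)))
  expect_lt(abs(a8 - 0.8), 0.1)
  # integrated white noise (random walk): alpha ~ 1.5
  a15 <- mean(vapply(1:10, function(s) {
    walk <- cumsum(simulateFGN(2^13, 0.5, seed = 200 + s))
    dfaAlpha(fitDFA(walk, fs = 250))
  }, numeric(1)))
  expect_lt(abs(a15 - 1.5), 0.1)
})

test_that("estimated exponent increases monotonically in the planted H", {
  hGrid <- c(0.55, 0.65, 0.75, 0.85)
  means <- vapply(hGrid, function(h)
    mean(vapply(1:10, function(s)
      dfaAlpha(fitDFA(simulateFGN(2^13, h, seed = 300 + s), fs = 250)),
      numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(abs(means - hGrid) < 0.1))
})

test_that("DFA is invariant to positive rescaling of the series", {
  x <- simulateFGN(8192, 0.7, seed = 5)
  r1 <- fitDFA(x, fs = 250)
  r2 <- fitDFA(37.5 * x, fs = 250)
  expect_equal(dfaAlpha(r1), dfaAlpha(r2), tolerance = 1e-12)
  expect_equal(rSquared(r1), rSquared(r2), tolerance = 1e-12)
})

test_that("log-log fits of scale-free series are tight", {
  for (s in 1:5) {
    r <- fitDFA(simulateFGN(2^13, 0.6 + 0.05 * s, seed = 400 + s), fs = 250)
    expect_gt(rSquared(r), 0.9)
  }
})

test_that("degenerate series are rejected", {
  expect_error(fitDFA(rep(0, 8192), fs = 250), "degenerate|constant")
})
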