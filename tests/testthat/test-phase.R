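fs <- 250

test_that("a pure tone yields a linear unwrapped phase ramp", {
  t <- (0:(8 * fs - 1)) / fs
  ph <- analyticPhase(cos(2 * pi * 10 * t), fs)
  interior <- (fs + 1):(7 * fs)  # exclude 1 s per edge
  slopes <- diff(ph@unwrapped[interior])
  expect_lt(max(abs(slopes - 2 * pi * 10 / fs)), 1e-3)
})

test_that("sine lags cosine by a quarter cycle", {
  t <- (0:(8 * fs - 1)) / fs
  pc <- analyticPhase(cos(2 * pi * 10 * t), fs)
  ps <- analyticPhase(sin(2 * pi * 10 * t), fs)
  interior <- (fs + 1):(7 * fs)
  off <- pc@unwrapped[interior] - ps@unwrapped[interior]
  expect_lt(max(abs(off - pi / 2)), 1e-3)
})

test_that("wrapped phase stays in [-pi, pi] and degenerate input errors", {
  set.seed(3)
  ph <- analyticPhase(rnorm(1000), fs)
  expect_true(all(abs(ph@wrapped) <= pi))
  expect_error(analyticPhase(numeric(100), fs), "degenerate")
  expect_error(analyticPhase(rep(2, 100), fs), "degenerate")
})

test_that("phase unwrapping adds 2*pi multiples exactly at wrap events", {
  expect_equal(unwrapPhase(c(0, pi - 0.1, -pi + 0.1)),
               c(0, pi - 0.1, pi + 0.1))
  smooth <- cumsum(runif(50, -1, 1))  # steps < pi: untouched
  smooth <- pmin(pmax(smooth, -pi), pi)
  expect_equal(unwrapPhase(smooth), smooth)
  set.seed(5)
  w <- runif(200, -pi, pi)
  u <- unwrapPhase(w)
  # re-wrapping the output recovers the input
  rewrap <- atan2(sin(u), cos(u))
  expect_equal(rewrap, atan2(sin(w), cos(w)), tolerance = 1e-12)
  expect_true(all(abs((u - w) / (2 * pi) -
                      round((u - w) / (2 * pi))) < 1e-9))
})

test_that("TV-PS of identical signals is identically zero", {
  set.seed(7)
  ph <- analyticPhase(rnorm(2000), fs)
  tv <- tvps(ph, ph)
  expect_equal(tv@values, numeric(length(ph@wrapped) - 1))
})

test_that("TV-PS of detuned tones equals the frequency difference", {
  t <- (0:(12 * fs - 1)) / fs
  pa <- analyticPhase(cos(2 * pi * 12 * t), fs)
  pb <- analyticPhase(cos(2 * pi * 10 * t), fs)
  tv <- tvps(pa, pb, trim = fs)  # 1 s edge trim
  expect_lt(max(abs(tv@values - 2 * pi * 2 / fs)), 1e-3)
})

test_that("TV-PS is antisymmetric and reconstructs the phase difference", {
  set.seed(9)
  pa <- analyticPhase(rnorm(1500), fs)
  pb <- analyticPhase(rnorm(1500), fs)
  ab <- tvps(pa, pb, trim = 10)
  ba <- tvps(pb, pa, trim = 10)
  expect_equal(ab@values, -ba@values)
  d <- (pa@unwrapped - pb@unwrapped)[11:1490]
  expect_equal(ab@initialPhaseDiff + cumsum(c(0, ab@values)), d,
               tolerance = 1e-12)
  expect_length(ab@values, length(d) - 1L)
  expect_error(tvps(pa, analyticPhase(rnorm(100), fs)), "lengths differ")
})

test_that("all-pairs TV-PS enumerates C(n, 2) series with a < b", {
  expect_equal(nrow(roiPairs(84)), 3486L)
  expect_equal(nrow(roiPairs(2)), 1L)
  set.seed(13)
  m <- matrix(rnorm(5 * 2000), 5)
  series <- allPairsTVPS(m, band = NULL, fs = fs)
  expect_length(series, 10L)
  expect_named(series, pairLabels <- paste0(roiPairs(5)[, 1], "-",
                                            roiPairs(5)[, 2]))
  for (tv in series) expect_lt(tv@roiA, tv@roiB)
  expect_error(allPairsTVPS(m[1, , drop = FALSE], band = NULL, fs = fs),
               "at least 2")
})

test_that("pipeline TV-PS matches the generator's planted increments", {
  # a ~10 Hz carrier cannot carry phase modulation faster than itself, so
  # the comparison aggregates increments to 0.1 s steps - well below the
  # smallest DFA window, so everything DFA sees is covered
  pr <- simulatePhaseCoupledPair(0.7, "alpha", 80, fs, seed = 21,
                                 noiseAmp = 0)
  trim <- fs
  pa <- analyticPhase(pr$a, fs)
  pb <- analyticPhase(pr$b, fs)
  measured <- tvps(pa, pb, trim = trim)@values
  planted <- -pr$increments[(trim + 2):(length(pr$a) - trim)]
  agg <- 25L
  k <- floor(length(measured) / agg)
  mAgg <- colSums(matrix(measured[1:(k * agg)], agg))
  pAgg <- colSums(matrix(planted[1:(k * agg)], agg))
  ks <- suppressWarnings(ks.test(mAgg, pAgg))
  expect_gt(ks$p.value, 0.01)
  # and tracks the planted trajectory, not just its law
  expect_gt(cor(mAgg, pAgg), 0.9)
})
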