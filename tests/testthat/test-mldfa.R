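test_that("the candidate set holds exactly 13 models", {
  cm <- candidateModels()
  expect_equal(nrow(cm), 13L)
  expect_true(all(c("linear", "quadratic", "cubic", "quartic", "quintic")
                  %in% cm$model))                       # degrees 1..5
  expect_true(all(c("root2", "root3", "root4") %in% cm$model))
  expect_true(all(c("exponential", "logarithmic") %in% cm$model))
  expect_true(all(c("spline2", "spline3", "spline4") %in% cm$model))
  expect_true(all(cm$nParams >= 2))
})

test_that("an exact line is fitted perfectly and accepted", {
  x <- seq(0, 1.2, length.out = 8)
  plot <- makePlot(x, 0.7 * x + 1.0)
  lin <- fitCandidate(plot, "linear")
  expect_lt(lin$rss, 1e-20)
  v <- validateScaleInvariance(plot)
  expect_true(isAccepted(v))
  expect_equal(v@winningModel, "linear")
  expect_equal(nrow(v@fits), 13L)
})

test_that("exact quadratic data defeats the linear model", {
  x <- seq(0, 1.2, length.out = 8)
  plot <- makePlot(x, 1 + 0.8 * (x - 0.5)^2)
  fits <- validateScaleInvariance(plot)@fits
  expect_lt(fits$rss[fits$model == "quadratic"], 1e-20)
  expect_lt(fits$aic[fits$model == "quadratic"],
            fits$aic[fits$model == "linear"])
  expect_false(isAccepted(validateScaleInvariance(plot)))
})

test_that("two-section spline fit equals exhaustive breakpoint search", {
  x <- seq(0, 1.4, length.out = 12)
  bp <- x[7]
  y <- 1 + 0.9 * x - 0.6 * pmax(x - bp, 0)  # kink exactly at a plot point
  plot <- makePlot(x, y)
  sp <- fitCandidate(plot, "spline2")
  expect_lt(sp$rss, 1e-20)
  # independent enumeration: try every interior point as the breakpoint
  set.seed(8)
  yN <- y + rnorm(12, 0, 0.03)
  plotN <- makePlot(x, yN)
  spN <- fitCandidate(plotN, "spline2")
  best <- min(vapply(x[2:11], function(b) {
    sum(residuals(lm(yN ~ x + pmax(x - b, 0)))^2)
  }, numeric(1)))
  expect_equal(spN$rss, best, tolerance = 1e-12)
})

test_that("higher-degree polynomials never fit worse than lower ones", {
  set.seed(31)
  for (i in 1:10) {
    x <- sort(runif(15, 0, 1.3))
    plot <- makePlot(x, 0.7 * x + rnorm(15, 0, 0.1))
    rss <- vapply(c("linear", "quadratic", "cubic", "quartic", "quintic"),
                  function(m) fitCandidate(plot, m)$rss, numeric(1))
    expect_true(all(diff(rss) <= 1e-12))
  }
})

test_that("a line plus small noise is still attributed to the line", {
  x <- seq(0, 1.18, length.out = 15)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    isAccepted(validateScaleInvariance(
      makePlot(x, 1 + 0.75 * x + rnorm(15, 0, 0.02))))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("scale-free series are accepted, crossover shapes rejected", {
  accFgn <- vapply(1:20, function(s) {
    plot <- fluctuationPlot(fitDFA(simulateFGN(2^14, 0.75, seed = s),
                                   fs = 250))
    isAccepted(validateScaleInvariance(plot))
  }, logical(1))
  expect_gte(mean(accFgn), 0.9)
  accOsc <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 2^14
    # sinusoid-modulated synchrony: a strong characteristic scale bends
    # the fluctuation plot
    x <- 2 * sin(2 * pi * (1:n) / 2000) + 0.2 * rnorm(n)
    plot <- fluctuationPlot(fitDFA(x, fs = 250))
    isAccepted(validateScaleInvariance(plot))
  }, logical(1))
  expect_lte(mean(accOsc), 0.1)
})

test_that("underdetermined fits are refused", {
  x <- seq(0, 1, length.out = 6)
  expect_error(fitCandidate(makePlot(x, x), "quintic"), "underdetermined")
})

test_that("acceptance percentage is the share of accepted verdicts", {
  expect_equal(acceptanceRate(c(TRUE, TRUE, FALSE, TRUE)), 75)
  expect_equal(acceptanceRate(rep(TRUE, 7)), 100)
  expect_equal(acceptanceRate(rep(FALSE, 3)), 0)
  expect_error(acceptanceRate(logical(0)), "at least one")
})
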