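test_that("with no covariate the edge F equals the squared pooled t", {
  set.seed(51)
  for (i in 1:50) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    y <- matrix(rnorm(n1 + n2), ncol = 1)
    g <- rep(c("g1", "g2"), c(n1, n2))
    st <- edgeFStats(y, g, pairs = rbind(c(1L, 2L)))
    tt <- t.test(y[g == "g1"], y[g == "g2"], var.equal = TRUE)
    expect_equal(st@fStat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(st@pUncorrected, tt$p.value, tolerance = 1e-10)
  }
})

test_that("edge F matches an explicit nested-model RSS-ratio fit", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(12:24, 1)
    y <- matrix(rnorm(3 * n), n, 3)
    g <- rep(c("g1", "g2"), length.out = n)
    covar <- cbind(rnorm(n), runif(n))
    st <- edgeFStats(y, g, covariates = covar, pairs = roiPairs(3))
    for (j in 1:3) {
      f0 <- naivePartialF(y[, j], g, covar)
      expect_lt(abs(st@fStat[j] - f0) / max(1, abs(f0)), 1e-10)
    }
  }
})

test_that("identical group values give F = 0 and matched sign screening", {
  y <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1)
  g <- rep(c("g1", "g2"), each = 4)
  st <- edgeFStats(y, g, pairs = rbind(c(1L, 2L)))
  expect_equal(st@fStat, 0)
  # direction screening: planted positive effect passes only group1>group2
  set.seed(53)
  y2 <- matrix(c(rnorm(6) + 3, rnorm(6)), ncol = 1)
  up <- edgeFStats(y2, g <- rep(c("g1", "g2"), each = 6),
                   pairs = rbind(c(1L, 2L)), direction = "group1>group2")
  down <- edgeFStats(y2, g, pairs = rbind(c(1L, 2L)),
                     direction = "group2>group1")
  expect_equal(nrow(primaryThreshold(up, 0.05)), 1L)
  expect_equal(nrow(primaryThreshold(down, 0.05)), 0L)
})

test_that("the primary threshold equals the parametric F quantile", {
  set.seed(54)
  y <- matrix(rnorm(20 * 45), 20)
  st <- edgeFStats(y, rep(c("g1", "g2"), each = 10), pairs = roiPairs(10))
  surv <- primaryThreshold(st, 0.05)
  # independent quantile: invert the F distribution function numerically
  fCrit <- uniroot(function(q) pf(q, 1, st@df[2]) - 0.95, c(0, 100),
                   tol = 1e-12)$root
  expect_equal(attr(surv, "fThreshold"), fCrit, tolerance = 1e-8)
  expect_setequal(which(st@fStat > fCrit),
                  which(st@pUncorrected < 0.05))
  expect_equal(nrow(surv), sum(st@fStat > fCrit))
  expect_error(primaryThreshold(st, 0), "strictly in")
})

test_that("hand-drawn graphs partition into the expected components", {
  comp <- findComponents(rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)),
                         f = c(1, 2, 4))
  expect_equal(sort(comp$extent), c(1L, 2L))
  expect_equal(sort(comp$intensity), c(3, 4))
  empty <- findComponents(matrix(integer(), ncol = 2), f = numeric())
  expect_equal(nrow(empty), 0L)
})

test_that("component finding matches label propagation on random graphs", {
  set.seed(55)
  for (i in 1:50) {
    nNodes <- 10L
    nEdges <- sample(3:14, 1)
    pairs <- roiPairs(nNodes)
    edges <- pairs[sample(nrow(pairs), nEdges), , drop = FALSE]
    f <- runif(nEdges)
    comp <- findComponents(edges, f)
    labels <- naiveComponents(edges, nNodes)
    expect_equal(sort(comp$extent), sort(as.vector(table(labels))))
    expect_equal(sum(comp$extent), nEdges)
    expect_equal(sum(comp$intensity), sum(f))
    # identical edge partitions
    got <- lapply(comp$edges, function(e)
      sort(paste(e[, 1], e[, 2], sep = "-")))
    want <- lapply(split(seq_along(labels), labels), function(ix)
      sort(paste(edges[ix, 1], edges[ix, 2], sep = "-")))
    expect_setequal(got, unname(want))
  }
})

test_that("NBS detects a planted component and controls its p floor", {
  set.seed(56)
  nPer <- 10L
  pairs <- roiPairs(8)
  y <- matrix(rnorm(2 * nPer * nrow(pairs)), 2 * nPer)
  planted <- which(pairs[, 1] == 1L & pairs[, 2] <= 5L)  # star on ROI 1
  y[1:nPer, planted] <- y[1:nPer, planted] + 2.5
  g <- rep(c("g1", "g2"), each = nPer)
  res <- nbsTest(y, g, pairs = pairs, nPerm = 200, seed = 1,
                 direction = "group1>group2")
  comp <- nbsComponents(res)
  expect_gt(nrow(comp), 0)
  expect_lt(comp$pFwer[1], 0.05)
  expect_true(all(comp$pFwer >= 1 / (res@nPerm + 1)))
  # planted edges are inside the detected component
  found <- paste(comp$edges[[1]][, 1], comp$edges[[1]][, 2], sep = "-")
  expect_gte(sum(paste(pairs[planted, 1], pairs[planted, 2], sep = "-")
                 %in% found), 3)
})

test_that("extent and intensity modes agree on component membership", {
  set.seed(57)
  pairs <- roiPairs(6)
  y <- matrix(rnorm(16 * nrow(pairs)), 16)
  y[1:8, 1:4] <- y[1:8, 1:4] + 1.2
  g <- rep(c("a", "b"), each = 8)
  rExt <- nbsTest(y, g, pairs = pairs, nPerm = 150, seed = 2,
                  sizeMode = "extent", direction = "group1>group2")
  rInt <- nbsTest(y, g, pairs = pairs, nPerm = 150, seed = 2,
                  sizeMode = "intensity", direction = "group1>group2")
  expect_equal(nbsComponents(rExt)$edges, nbsComponents(rInt)$edges)
  expect_equal(nbsComponents(rExt)$extent, nbsComponents(rInt)$extent)
})

test_that("a constant covariate reproduces the no-covariate analysis", {
  set.seed(58)
  y <- matrix(rnorm(18 * 10), 18)
  g <- rep(c("g1", "g2"), each = 9)
  a <- edgeFStats(y, g, covariates = rep(5, 18), pairs = roiPairs(5))
  b <- edgeFStats(y, g, pairs = roiPairs(5))
  expect_equal(a@fStat, b@fStat, tolerance = 1e-12)
  expect_equal(a@df, b@df)
})

test_that("NBS results are reproducible from the seed", {
  set.seed(59)
  y <- matrix(rnorm(14 * 15), 14)
  g <- rep(c("g1", "g2"), each = 7)
  r1 <- nbsTest(y, g, pairs = roiPairs(6), nPerm = 120, seed = 99)
  r2 <- nbsTest(y, g, pairs = roiPairs(6), nPerm = 120, seed = 99)
  expect_identical(r1@nullMaxSize, r2@nullMaxSize)
  expect_identical(nbsComponents(r1), nbsComponents(r2))
})

test_that("degenerate designs are rejected", {
  y <- matrix(rnorm(12), ncol = 2)
  expect_error(edgeFStats(y, rep("one", 6), pairs = roiPairs(2)),
               "two values")
  expect_error(edgeFStats(y, c("a", "a", "a", "a", "b", "b"),
                          pairs = roiPairs(2)), "at least 3")
  g <- rep(c("a", "b"), each = 3)
  expect_error(edgeFStats(matrix(rnorm(6), ncol = 1), g,
                          covariates = as.numeric(g == "a"),
                          pairs = rbind(c(1L, 2L))), "collinear")
})
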