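# independent brute-force oracles used across test files; these stay
# deliberately naive (explicit loops, explicit per-window fits) so they do
# not share code paths with the implementation they check

# fluctuation function: explicit window loop with per-window polyfit
naiveFluctuation <- function(profile, tau, overlap = 0.5) {
  n <- length(profile)
  step <- tau * (1 - overlap)
  sds <- c()
  k <- 0
  repeat {
    start <- floor(k * step)
    if (start + tau > n) break
    w <- profile[(start + 1):(start + tau)]
    t <- 1:tau
    fit <- lm(w ~ t)
    r <- residuals(fit)
    sds <- c(sds, sqrt(mean(r^2)))
    k <- k + 1
  }
  mean(sds)
}

# partial F of the group column by explicitly fitting both nested models
naivePartialF <- function(y, group, covariates = NULL) {
  g <- as.numeric(group == levels(as.factor(group))[1])
  df <- data.frame(y = y, g = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    for (j in seq_len(ncol(covariates))) df[[paste0("c", j)]] <- covariates[, j]
    full <- lm(y ~ ., data = df)
    red <- lm(y ~ . - g, data = df)
  } else {
    full <- lm(y ~ g, data = df)
    red <- lm(y ~ 1, data = df)
  }
  rssF <- sum(residuals(full)^2)
  rssR <- sum(residuals(red)^2)
  df2 <- nrow(df) - length(coef(full))
  (rssR - rssF) / (rssF / df2)
}

# connected components by label propagation to a fixed point
naiveComponents <- function(edges, nNodes) {
  lab <- seq_len(nNodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[a] <- m; lab[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # per-edge component label
  lab[edges[, 1]]
}

# build a FluctuationPlot directly from (x, y) points
makePlot <- function(x, y) {
  methods::new("FluctuationPlot", tauS = 10^x,
               tauSamples = as.integer(round(10^x * 250)),
               log10Tau = x, log10F = y)
}
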