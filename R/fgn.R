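#' Autocovariance of fractional Gaussian noise
#'
#' Closed-form autocovariance of unit-variance fractional Gaussian noise
#' (fGn) with Hurst exponent H:
#' gamma(k) = (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)) / 2.
#'
#' @param k integer lag(s), may be negative.
#' @param hurst Hurst exponent in (0, 1).
#' @return autocovariance value(s).
#' @export
fgnAutocovariance <- function(k, hurst) {
  if (hurst <= 0 || hurst >= 1) stop("'hurst' must lie strictly in (0, 1)")
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Simulate fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary unit-variance fGn with the Davies-Harte
#' circulant embedding: the target autocovariance is embedded in a
#' circulant matrix whose eigenvalues (obtained by FFT) are non-negative
#' for fGn, so the finite-sample covariance of the output is exactly the
#' closed form of [fgnAutocovariance] rather than an approximation.
#'
#' @param n series length (>= 2).
#' @param hurst Hurst exponent in (0, 1); 0.5 gives white noise,
#'   0.5 < H < 1 persistent long-range correlation.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return numeric series of length \code{n} with mean 0 and variance 1 in
#'   expectation.
#' @examples
#' x <- simulateFGN(1024, hurst = 0.8, seed = 1)
#' @export
simulateFGN <- function(n, hurst, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (hurst <= 0 || hurst >= 1) stop("'hurst' must lie strictly in (0, 1)")
  withSeed(seed, {
    m <- n
    g <- fgnAutocovariance(0:m, hurst)
    crow <- c(g[1:(m + 1L)], g[m:2])          # circulant first row, length 2m
    lambda <- Re(stats::fft(crow))
    if (min(lambda) < -1e-8 * max(lambda))
      stop("circulant embedding is not non-negative definite")
    lambda[lambda < 0] <- 0
    two_m <- 2L * m
    z <- stats::rnorm(two_m)
    w <- complex(length.out = two_m)
    w[1L] <- sqrt(lambda[1L]) * z[1L]
    w[m + 1L] <- sqrt(lambda[m + 1L]) * z[2L]
    if (m > 1L) {
      ks <- 2:m
      re <- z[2L * ks - 1L]
      im <- z[2L * ks]
      w[ks] <- sqrt(lambda[ks] / 2) * complex(real = re, imaginary = im)
      w[two_m + 2L - ks] <- Conj(w[ks])
    }
    x <- Re(stats::fft(w)) / sqrt(two_m)
    x[seq_len(n)]
  })
}
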