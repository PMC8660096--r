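# internal helpers shared across modules

# Evaluate `code` under a temporary, fully specified RNG state; the caller's
# RNG state is untouched. seed = NULL evaluates in the current state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' All unordered ROI pairs
#'
#' Enumerates the C(n, 2) unordered pairs of n ROIs in lexicographic order
#' with a < b, the edge ordering used throughout the package.
#'
#' @param n number of ROIs (>= 2).
#' @return integer matrix with columns \code{a}, \code{b} and C(n, 2) rows.
#' @examples
#' nrow(roiPairs(84))  # 3486
#' @export
roiPairs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  a <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  b <- sequence((n - 1L):1L, from = 2:n)
  cbind(a = a, b = b)
}

# canonical "a-b" label for edge columns in tables
pairLabels <- function(pairs) paste0(pairs[, 1], "-", pairs[, 2])

stopifnotScalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0))
    stop(sprintf("'%s' must be a single %s number", name,
                 if (positive) "positive" else "finite"))
  invisible(x)
}
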