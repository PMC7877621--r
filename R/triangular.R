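#' Sample from a triangular distribution by inverse-CDF
#'
#' Three-point expert estimates (worst, most-likely, best) define a triangular
#' distribution on `[low, high]` with mode `mode`. Sampling is by inversion of
#' the closed-form CDF, so draws are a deterministic function of the supplied
#' uniform stream -- a requirement for common-random-number reuse across
#' portfolio evaluations. Degenerate specs (`low == high`) are point masses.
#'
#' All arguments are vectorised and recycled to a common length, so one call
#' can draw from a different triangular per element (used when each Monte
#' Carlo iteration picks a different reviewer).
#'
#' @param n Number of draws; ignored when `u` is supplied.
#' @param low,mode,high Triangular parameters, `low <= mode <= high`.
#' @param u Optional uniform(0,1) variates to invert; defaults to `runif(n)`.
#' @return Numeric vector of draws in `[low, high]`.
#' @export
sample_triangular <- function(n, low, mode, high, u = NULL) {
  validate_triangular(low, mode, high)
  if (is.null(u)) u <- stats::runif(n)
  k <- length(u)
  low <- rep_len(low, k); mode <- rep_len(mode, k); high <- rep_len(high, k)
  rng <- high - low
  out <- numeric(k)
  pt <- rng == 0
  out[pt] <- low[pt]
  if (any(!pt)) {
    l <- low[!pt]; m <- mode[!pt]; h <- high[!pt]; uu <- u[!pt]; r <- rng[!pt]
    fc <- (m - l) / r  # CDF at the mode
    lower <- uu < fc
    res <- numeric(length(uu))
    res[lower] <- l[lower] + sqrt(uu[lower] * r[lower] * (m[lower] - l[lower]))
    res[!lower] <- h[!lower] -
      sqrt((1 - uu[!lower]) * r[!lower] * (h[!lower] - m[!lower]))
    out[!pt] <- res
  }
  out
}

#' Mean of a triangular distribution
#' @param low,mode,high Triangular parameters.
#' @return `(low + mode + high) / 3`.
#' @export
triangular_mean <- function(low, mode, high) (low + mode + high) / 3

validate_triangular <- function(low, mode, high) {
  if (any(low > mode + 1e-12) || any(mode > high + 1e-12)) {
    stop("triangular spec must satisfy low <= mode <= high", call. = FALSE)
  }
  invisible(TRUE)
}
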