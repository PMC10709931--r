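#' Distance profile of a pattern against a glucose series
#'
#' Computes, for every window start position of the series, the z-normalized
#' Euclidean distance between the query pattern and that window — the
#' MASS algorithm: sliding dot products via FFT convolution plus rolling
#' moments, O(m log m) per contiguous segment. Positions whose window
#' crosses a gap, runs past a contiguous segment, or has zero variance
#' receive the sentinel `Inf`, which removes them from all downstream
#' candidate selection.
#'
#' @param glucose a [GlucoseSeries-class] spanning `m` grid positions.
#' @param pattern a [ResponsePattern-class] (or numeric vector) of length
#'   `n`; it is z-normalized internally.
#' @return A [DistanceProfile-class] of length `m - n + 1`.
#' @seealso [bruteForceProfile()] for the O(m n) oracle.
#' @export
distanceProfile <- function(glucose, pattern) {
  pid <- if (is(pattern, "ResponsePattern")) pattern@patternId else NA_integer_
  q <- if (is(pattern, "ResponsePattern")) pattern@values else as.numeric(pattern)
  n <- length(q)
  if (n < 2L) stop("pattern length must be >= 2")
  q <- znormalize(q)
  if (attr(q, "degenerate")) stop("pattern has zero variance")
  v <- glucose@values
  m <- length(v)
  if (m < n) stop("pattern longer than the series")
  prof <- rep(Inf, m - n + 1L)

  segs <- .contiguousSegments(v)
  anyFit <- FALSE
  for (s in segs) {
    L <- s[2] - s[1] + 1L
    if (L < n) next
    anyFit <- TRUE
    x <- v[s[1]:s[2]]
    qt <- stats::convolve(x, as.numeric(q), type = "filter")
    cs <- cumsum(c(0, x))
    cs2 <- cumsum(c(0, x^2))
    win <- seq_len(L - n + 1L)
    mu <- (cs[win + n] - cs[win]) / n
    sig2 <- (cs2[win + n] - cs2[win]) / n - mu^2
    sig <- sqrt(pmax(sig2, 0))
    d2 <- 2 * n - 2 * qt / sig            # q has zero mean, sum(q^2) = n
    d <- pmin(sqrt(pmax(d2, 0)), 2 * sqrt(n))
    d[sig < 1e-8] <- Inf
    prof[s[1] + win - 1L] <- d
  }
  if (!anyFit)
    stop("no contiguous gap-free segment is as long as the pattern (n = ",
         n, ")")
  new("DistanceProfile", patternId = as.integer(pid), n = as.integer(n),
      values = prof)
}

# runs of non-NA positions as list of c(start, end)
.contiguousSegments <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mapply(function(s, e) c(s, e), starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

#' Brute-force distance profile (verification oracle)
#'
#' Direct O(m n) computation: each window is z-normalized explicitly and its
#' Euclidean distance to the z-normalized pattern taken. Exists to verify
#' [distanceProfile()]; results agree to ~1e-8.
#'
#' @inheritParams distanceProfile
#' @return A [DistanceProfile-class].
#' @export
bruteForceProfile <- function(glucose, pattern) {
  pid <- if (is(pattern, "ResponsePattern")) pattern@patternId else NA_integer_
  q <- if (is(pattern, "ResponsePattern")) pattern@values else as.numeric(pattern)
  n <- length(q)
  if (n < 2L) stop("pattern length must be >= 2")
  q <- znormalize(q)
  if (attr(q, "degenerate")) stop("pattern has zero variance")
  v <- glucose@values
  m <- length(v)
  if (m < n) stop("pattern longer than the series")
  prof <- rep(Inf, m - n + 1L)
  any_ok <- FALSE
  for (i in seq_len(m - n + 1L)) {
    w <- v[i:(i + n - 1L)]
    if (anyNA(w)) next
    any_ok <- TRUE
    z <- znormalize(w)
    if (attr(z, "degenerate")) next
    prof[i] <- sqrt(sum((z - q)^2))
  }
  if (!any_ok)
    stop("no contiguous gap-free segment is as long as the pattern (n = ",
         n, ")")
  new("DistanceProfile", patternId = as.integer(pid), n = as.integer(n),
      values = prof)
}
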