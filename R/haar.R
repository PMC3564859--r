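#' Orthonormal Haar discrete wavelet transform
#'
#' Full decimated Haar DWT of a power-of-two-length vector, in the
#' orthonormal convention: each level keeps averages `(a + b)/sqrt(2)` and
#' differences `(a - b)/sqrt(2)` of adjacent pairs. Orthonormality is what
#' makes Euclidean distance between (possibly coefficient-thinned)
#' transforms lower-bound the Euclidean distance between the raw series —
#' the property required for the representation to be safe for indexing.
#'
#' Coefficients are ordered as the single coarsest approximation
#' coefficient followed by detail coefficients from coarsest to finest
#' scale. Under this ordering trailing zero-padding of the input
#' contaminates the trailing (finest, latest-time) symbols, which is why the
#' representation pipeline truncates from the end.
#'
#' @param x Numeric vector whose length is a power of two (pad first with
#'   [pad_to_power_of_two()]).
#' @return Numeric vector of Haar coefficients, same length as `x`; total
#'   energy (sum of squares) is preserved.
#' @examples
#' haar_dwt(c(1, 1, 1, 1))   # c(2, 0, 0, 0)
#' x <- rnorm(16)
#' all.equal(sum(x^2), sum(haar_dwt(x)^2))
#' @export
haar_dwt <- function(x) {
  L <- length(x)
  if (!is_power_of_two(L)) {
    abort(sprintf(
      "length %d is not a power of two; call pad_to_power_of_two() first", L))
  }
  if (any(!is.finite(x))) abort("input must be finite")
  out <- numeric(L)
  a <- x
  pos <- L
  while (length(a) > 1) {
    od <- a[seq(1, length(a), by = 2)]
    ev <- a[seq(2, length(a), by = 2)]
    d <- (od - ev) / sqrt(2)
    a <- (od + ev) / sqrt(2)
    out[(pos - length(d) + 1):pos] <- d
    pos <- pos - length(d)
  }
  out[1] <- a
  out
}

#' Inverse orthonormal Haar transform
#'
#' Exact inverse of [haar_dwt()]; reconstructs the original series from a
#' full coefficient vector.
#'
#' @param w Coefficient vector as returned by [haar_dwt()].
#' @return The reconstructed series.
#' @export
inv_haar_dwt <- function(w) {
  L <- length(w)
  if (!is_power_of_two(L)) abort("coefficient length must be a power of two")
  a <- w[1]
  len <- 1L
  pos <- 2L
  while (len < L) {
    d <- w[pos:(pos + len - 1L)]
    up <- numeric(2L * len)
    up[seq(1, 2L * len, by = 2)] <- (a + d) / sqrt(2)
    up[seq(2, 2L * len, by = 2)] <- (a - d) / sqrt(2)
    a <- up
    pos <- pos + len
    len <- len * 2L
  }
  a
}
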