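#' Pipeline settings for SMETS comparisons
#'
#' Bundles every tunable of the preprocessing and distance pipeline so the
#' same settings are applied consistently to all series entering a
#' comparison. Two series (or a collection) are only comparable when built
#' with identical settings; functions check this and refuse mixed pipelines.
#'
#' @param normalize Z-normalize each component (subtract mean, divide by the
#'   population standard deviation) before any transform. Constant components
#'   map to all-zero traces rather than erroring, so static variables survive
#'   preprocessing. Default `TRUE`.
#' @param wavelet Use the truncated Haar wavelet representation for component
#'   distances. When `FALSE`, Euclidean distances are computed on the raw
#'   (normalized, zero-padded) series instead. Default `TRUE`.
#' @param k Number of largest-magnitude Haar coefficients retained per
#'   component. Capped at the padded series length. Default 16.
#' @param truncate_to Length the retained representation is cut back to by
#'   dropping trailing (largest transform index) symbols, which are the ones
#'   biased by the zero padding. `NULL` means one symbol is dropped, i.e.
#'   `k - 1` (15 under the defaults). Use `k` to disable truncation.
#' @param entropy_bins Number of equal-width bins used to discretize values
#'   before computing Shannon entropy. `0` (default) uses exact value
#'   frequencies, faithful to entropy over the observed data points; real
#'   measurements with no repeated values then have the maximal entropy
#'   `log(q)`.
#' @param linkage Agglomerative linkage criterion for
#'   [smets_hclust()]: `"average"` (default), `"single"` or `"complete"`.
#' @return A list of class `smets_control`.
#' @seealso [smets()], [smets_distance()], [wavelet_represent()]
#' @examples
#' smets_control()
#' smets_control(wavelet = FALSE)           # raw-series backend
#' smets_control(k = 4, truncate_to = 4)    # tiny untruncated representation
#' @export
smets_control <- function(normalize = TRUE,
                          wavelet = TRUE,
                          k = 16,
                          truncate_to = NULL,
                          entropy_bins = 0,
                          linkage = c("average", "single", "complete")) {
  k <- as.integer(k)
  if (k < 1) abort("`k` must be a positive integer")
  if (!is.null(truncate_to)) {
    truncate_to <- as.integer(truncate_to)
    if (truncate_to < 1) abort("`truncate_to` must be a positive integer")
    if (truncate_to > k) abort("`truncate_to` cannot exceed `k`")
  }
  entropy_bins <- as.integer(entropy_bins)
  if (entropy_bins < 0) abort("`entropy_bins` must be >= 0")
  structure(
    list(normalize = isTRUE(normalize),
         wavelet = isTRUE(wavelet),
         k = k,
         truncate_to = truncate_to,
         entropy_bins = entropy_bins,
         linkage = match.arg(linkage)),
    class = "smets_control"
  )
}

#' @export
print.smets_control <- function(x, ...) {
  cat("SMETS pipeline settings\n")
  cat("  normalize:   ", x$normalize, "\n")
  if (x$wavelet) {
    tt <- if (is.null(x$truncate_to)) sprintf("%d (k - 1)", x$k - 1L)
          else as.character(x$truncate_to)
    cat("  backend:      Haar wavelet (k =", x$k, ", truncate to", tt, ")\n")
  } else {
    cat("  backend:      raw series (Euclidean)\n")
  }
  cat("  entropy bins:", if (x$entropy_bins == 0) "exact values"
      else x$entropy_bins, "\n")
  cat("  linkage:     ", x$linkage, "\n")
  invisible(x)
}

control_identical <- function(a, b) {
  identical(unclass(a)[c("normalize", "wavelet", "k", "truncate_to")],
            unclass(b)[c("normalize", "wavelet", "k", "truncate_to")])
}
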