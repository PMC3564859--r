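is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

next_power_of_two <- function(n) {
  stopifnot(n >= 1)
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' Aggregate matched component distances with a p-norm
#'
#' Computes \eqn{(\sum_i d_i^p)^{1/p}}. In a SMETS comparison `p` is set to
#' `n`, the dimension of the smaller multivariate series, so the norm used
#' changes from pair to pair within a collection. Evaluated in a scaled form
#' so large `p` does not overflow.
#'
#' @param d Numeric vector of non-negative matched distances.
#' @param p Norm order; defaults to `length(d)`.
#' @return A single non-negative number.
#' @examples
#' p_norm_distance(c(3, 4))       # 5
#' p_norm_distance(c(0, 0, 0))    # 0
#' @export
p_norm_distance <- function(d, p = length(d)) {
  if (length(d) == 0) return(0)
  if (any(d < 0)) abort("matched distances must be non-negative")
  if (p < 1) abort("`p` must be >= 1")
  mx <- max(d)
  if (mx == 0) return(0)
  mx * sum((d / mx)^p)^(1 / p)
}

# shared validation for the canonical long layout
check_ts_tbl <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame in long layout", arg))
  }
  need <- c("series", "component", "time", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (anyNA(data$value) || any(!is.finite(data$value))) {
    bad <- unique(data$component[!is.finite(data$value) | is.na(data$value)])
    abort(sprintf("non-finite values in component(s): %s",
                  paste(bad, collapse = ", ")))
  }
  invisible(data)
}
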