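#' Coerce a table of time courses to the canonical long layout
#'
#' The package represents one or more multivariate time series as a long
#' tibble with columns `series` (which multivariate series, i.e. which
#' model), `component` (which univariate variable within it), `time` and
#' `value`. Samples are assumed equally spaced; `time` is kept for ordering
#' and plotting only.
#'
#' Wide tables (one `time` column plus one column per component) are
#' reshaped; long tables are validated and passed through. Within a series
#' all components must be observed at the same number of time points and
#' component names must be unique.
#'
#' @param data A data frame: either already long (`series`, `component`,
#'   `time`, `value`) or wide (`time` plus component columns).
#' @param series Series label to attach when `data` is wide (or long without
#'   a `series` column).
#' @return A tibble with columns `series`, `component`, `time`, `value`,
#'   ordered by series, component and time.
#' @examples
#' wide <- data.frame(time = 0:3, x = c(1, 2, 3, 4), y = 0)
#' as_ts_tbl(wide, series = "toy")
#' @export
as_ts_tbl <- function(data, series = "series1") {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  long_cols <- c("component", "time", "value")
  if (all(long_cols %in% names(data))) {
    if (!"series" %in% names(data)) data$series <- series
    out <- tibble::as_tibble(data)[, c("series", "component", "time", "value")]
  } else {
    if (!"time" %in% names(data)) {
      abort("wide input must have a `time` column")
    }
    if (ncol(data) < 2) abort("wide input needs at least one component column")
    out <- tidyr::pivot_longer(tibble::as_tibble(data), -"time",
                               names_to = "component", values_to = "value")
    out$series <- series
    out <- out[, c("series", "component", "time", "value")]
  }
  out$series <- as.character(out$series)
  out$component <- as.character(out$component)
  out$value <- as.double(out$value)
  check_ts_tbl(out)
  out <- dplyr::arrange(out, .data$series, .data$component, .data$time)
  lens <- dplyr::summarise(dplyr::group_by(out, .data$series, .data$component),
                           q = dplyr::n(), .groups = "drop_last")
  bad <- dplyr::filter(dplyr::summarise(lens, k = dplyr::n_distinct(.data$q),
                                        .groups = "drop"), .data$k > 1)
  if (nrow(bad) > 0) {
    abort(sprintf("components of series %s differ in length",
                  paste(unique(bad$series), collapse = ", ")))
  }
  dup <- duplicated(out[, c("series", "component", "time")])
  if (any(dup)) abort("duplicated (series, component, time) records")
  out
}

#' Read one multivariate time series from a delimited text file
#'
#' Expects a header row naming the components, a first column of time stamps
#' and one column per component. The time column must be strictly
#' increasing; it is dropped after this check because the method treats
#' samples as equally spaced (a warning is issued for visibly non-uniform
#' spacing). Missing cells are an error.
#'
#' @param path Path to a CSV or TSV file (delimiter guessed from the
#'   extension, override with `delim`).
#' @param series Series label; defaults to the file name without extension.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return A long tibble as produced by [as_ts_tbl()].
#' @export
read_series_csv <- function(path, series = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE))
      "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) abort(sprintf("%s: need a time column plus components", path))
  if (anyNA(raw)) abort(sprintf("%s: missing cells are not allowed", path))
  tvec <- as.double(raw[[1]])
  if (any(diff(tvec) <= 0)) {
    abort(sprintf("%s: time column must be strictly increasing", path))
  }
  dt <- diff(tvec)
  if (length(dt) > 1 &&
      (max(dt) - min(dt)) > 1e-8 * max(abs(dt))) {
    warn(sprintf(
      "%s: non-uniform time spacing; samples are treated as equally spaced",
      path))
  }
  wide <- raw
  names(wide)[1] <- "time"
  wide$time <- tvec
  series <- series %||% sub("\\.[^.]*$", "", basename(path))
  as_ts_tbl(as.data.frame(wide), series = series)
}

znorm_vec <- function(x, name = "series") {
  if (any(!is.finite(x))) {
    abort(sprintf("non-finite values in component %s", name))
  }
  if (length(x) < 2) abort("z-normalization needs at least 2 points")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))   # population form
  if (s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

#' Z-normalize every component of a collection
#'
#' Subtracts the mean and divides by the population standard deviation of
#' each component, so that only shape differences remain between series.
#' Constant components become all-zero traces instead of erroring: static
#' variables are legitimate model behavior and must survive preprocessing.
#'
#' @param data A long tibble (see [as_ts_tbl()]).
#' @return A tibble of the same shape with normalized `value`s.
#' @examples
#' d <- as_ts_tbl(data.frame(time = 0:2, x = c(1, 2, 3), c = 7))
#' z_normalize(d)
#' @export
z_normalize <- function(data) {
  check_ts_tbl(data)
  dplyr::mutate(
    dplyr::group_by(data, .data$series, .data$component),
    value = znorm_vec(.data$value, .data$component[1])
  ) |> dplyr::ungroup()
}

#' Zero-pad components to a power-of-two length
#'
#' The Haar transform requires power-of-two lengths, so each component is
#' extended with trailing zeros up to `length_out` (by default the next
#' power of two of its own length; a collection being compared is padded to
#' a common length). Appended time stamps continue the observed spacing.
#'
#' @param data A long tibble (see [as_ts_tbl()]).
#' @param length_out Target length; must be a power of two at least the
#'   longest component. `NULL` pads each series to its own next power of two.
#' @return A padded long tibble.
#' @examples
#' d <- as_ts_tbl(data.frame(time = 0:5, x = 1:6))
#' nrow(pad_to_power_of_two(d))   # 8
#' @export
pad_to_power_of_two <- function(data, length_out = NULL) {
  check_ts_tbl(data)
  if (!is.null(length_out) && !is_power_of_two(length_out)) {
    abort("`length_out` must be a power of two")
  }
  pad_one <- function(df) {
    q <- nrow(df)
    L <- length_out %||% next_power_of_two(q)
    if (L < q) abort("`length_out` is shorter than a component")
    if (L == q) return(df)
    dt <- if (q > 1) df$time[2] - df$time[1] else 1
    extra <- tibble::tibble(series = df$series[1], component = df$component[1],
                            time = df$time[q] + dt * seq_len(L - q),
                            value = 0)
    dplyr::bind_rows(df, extra)
  }
  data <- dplyr::arrange(data, .data$series, .data$component, .data$time)
  parts <- split(data, interaction(data$series, data$component, drop = TRUE))
  out <- dplyr::bind_rows(purrr::map(parts, pad_one))
  dplyr::arrange(out, .data$series, .data$component, .data$time)
}

# split a long tibble into a named list of q x d value matrices
ts_split <- function(data) {
  check_ts_tbl(data)
  data <- dplyr::arrange(data, .data$series, .data$component, .data$time)
  lapply(split(data, data$series), function(df) {
    comps <- split(df$value, df$component)
    q <- unique(lengths(comps))
    if (length(q) > 1) abort("components differ in length within a series")
    do.call(cbind, comps)
  })
}
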