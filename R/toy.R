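#' Generate a synthetic toy model
#'
#' Builds one multivariate series from archetypal dynamic behaviors:
#' sinusoidal oscillators (optionally damped), exponential relaxations,
#' constant traces, and stock-like Gaussian random walks. These emulate the
#' qualitative behaviors of small dynamic models — sustained or damped
#' oscillations, monotone approaches to steady state, and static variables —
#' that the comparison method is designed to tell apart.
#'
#' Components are deterministic functions of their index and the shared
#' settings, so two models generated with the same oscillator settings share
#' bit-identical oscillating components regardless of how many other
#' components they have (this is what makes penalty-only comparisons
#' possible). Randomness enters only through `noise` and random-walk
#' components, both driven by `seed`.
#'
#' @param name Series label.
#' @param n_oscillating,n_monotonic,n_constant,n_random_walk Component
#'   counts per behavior class; at least one in total.
#' @param length Number of time points `q` (>= 4). Default 64.
#' @param period Oscillation period in samples. Default `length / 4`.
#' @param amplitude Oscillation amplitude. Default 1.
#' @param damping Exponential damping rate of oscillators per sample
#'   (0 = sustained). Default 0.
#' @param decay Relaxation rate per sample for monotonic components.
#'   Default 0.08.
#' @param noise Standard deviation of additive Gaussian noise on every
#'   component. Default 0 (the idealized toy systems).
#' @param seed Integer seed for noise and random walks; `NULL` leaves the
#'   RNG state alone.
#' @return A long tibble (see [as_ts_tbl()]). Components are named
#'   `osc1...`, `mono1...`, `const1...`, `rw1...`.
#' @examples
#' a <- generate_toy_model("A", n_oscillating = 1, n_constant = 2)
#' dplyr::count(a, component)
#' @export
generate_toy_model <- function(name = "model",
                               n_oscillating = 0, n_monotonic = 0,
                               n_constant = 0, n_random_walk = 0,
                               length = 64, period = length / 4,
                               amplitude = 1, damping = 0,
                               decay = 0.08, noise = 0, seed = NULL) {
  counts <- c(n_oscillating, n_monotonic, n_constant, n_random_walk)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("need at least one component with non-negative counts")
  }
  q <- as.integer(length)
  if (q < 4) abort("`length` must be at least 4")
  if (noise < 0) abort("`noise` must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- seq_len(q) - 1

  comp <- list()
  for (i in seq_len(n_oscillating)) {
    comp[[paste0("osc", i)]] <-
      amplitude * exp(-damping * t) * sin(2 * pi * t / period + (i - 1) * pi / 4)
  }
  for (i in seq_len(n_monotonic)) {
    comp[[paste0("mono", i)]] <- exp(-decay * (1 + (i - 1) / 2) * t)
  }
  for (i in seq_len(n_constant)) {
    comp[[paste0("const", i)]] <- rep(i, q)
  }
  for (i in seq_len(n_random_walk)) {
    comp[[paste0("rw", i)]] <- cumsum(stats::rnorm(q))
  }
  if (noise > 0) {
    comp <- lapply(comp, function(x) x + stats::rnorm(q, sd = noise))
  }
  tibble::tibble(
    series = name,
    component = base::rep(names(comp), each = q),
    time = base::rep(t, times = base::length(comp)),
    value = unlist(comp, use.names = FALSE))
}

#' Generate a collection of toy models from a spec table
#'
#' Row-wise wrapper around [generate_toy_model()]: each row of `specs`
#' supplies (a subset of) its arguments, with `...` giving shared defaults.
#' Seeds, when not given per row, are derived deterministically from a
#' shared `seed` so the collection is reproducible as a whole.
#'
#' @param specs A data frame with a `name` column plus any
#'   [generate_toy_model()] arguments as columns.
#' @param ... Shared arguments applied to every row (row values win).
#' @param seed Optional collection seed; row i uses `seed + i` unless the
#'   row carries its own.
#' @return A long tibble holding all generated series.
#' @examples
#' specs <- tibble::tibble(name = c("A", "B"), n_constant = c(2, 4))
#' generate_toy_collection(specs, n_oscillating = 1, length = 32)
#' @export
generate_toy_collection <- function(specs, ..., seed = NULL) {
  if (!is.data.frame(specs) || !"name" %in% names(specs)) {
    abort("`specs` must be a data frame with a `name` column")
  }
  if (anyDuplicated(specs$name)) abort("duplicate series names in `specs`")
  shared <- list(...)
  rows <- purrr::map(seq_len(nrow(specs)), function(i) {
    args <- as.list(specs[i, , drop = FALSE])
    args <- args[!vapply(args, function(v) is.na(v)[1], logical(1))]
    args <- utils::modifyList(shared, args)
    names(args)[names(args) == "name"] <- "name"
    if (is.null(args$seed) && !is.null(seed)) args$seed <- as.integer(seed) + i
    do.call(generate_toy_model, args)
  })
  dplyr::bind_rows(rows)
}
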