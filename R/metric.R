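entropy_vec <- function(x, bins = 0) {
  q <- length(x)
  if (q < 1) abort("entropy needs at least one observation")
  if (bins > 0) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(0)
    x <- findInterval(x, seq(rng[1], rng[2], length.out = bins + 1),
                      rightmost.closed = TRUE)
  }
  f <- tabulate(factor(x)) / q
  -sum(f * log(f))
}

#' Shannon entropy of each component
#'
#' Empirical Shannon entropy (natural log) of the value distribution of a
#' univariate component: `H = -sum f(v) log f(v)` over the distinct observed
#' values `v` with empirical frequencies `f(v)`. Constant traces have
#' entropy 0; a component whose `q` values are all distinct has the maximal
#' entropy `log(q)`. For continuous measurements where exact frequencies
#' degenerate to the uniform case, `bins` discretizes values into that many
#' equal-width bins first.
#'
#' In a SMETS comparison entropies are computed on the normalized,
#' pre-padding series: entropy is defined over the observed data points, and
#' padding zeros are bookkeeping, not observations.
#'
#' @param data A long tibble (see [as_ts_tbl()]).
#' @param bins Number of equal-width bins (0 = exact values, the default).
#' @return A tibble `series`, `component`, `q`, `entropy` (nats).
#' @examples
#' d <- as_ts_tbl(data.frame(time = 0:3, a = c(1, 1, 2, 2), c = 5))
#' series_entropy(d)   # a: log(2); c: 0
#' @export
series_entropy <- function(data, bins = 0) {
  check_ts_tbl(data)
  dplyr::summarise(
    dplyr::group_by(data, .data$series, .data$component),
    q = dplyr::n(),
    entropy = entropy_vec(.data$value, bins = bins),
    .groups = "drop")
}

# greedy partial matching on an explicit n x m cross-distance matrix
# (rows = smaller series). Ties break lexicographically by (row, col).
greedy_match_matrix <- function(D) {
  n <- nrow(D)
  m <- ncol(D)
  if (n > m) abort("rows of the cross-distance matrix must be the smaller side")
  W <- D
  pairs <- matrix(0L, nrow = n, ncol = 2)
  dist <- numeric(n)
  for (step in seq_len(n)) {
    mn <- min(W)
    hits <- which(W == mn, arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], , drop = TRUE]
    pairs[step, ] <- c(hit[["row"]], hit[["col"]])
    dist[step] <- D[hit[["row"]], hit[["col"]]]
    W[hit[["row"]], ] <- Inf
    W[, hit[["col"]]] <- Inf
  }
  unmatched <- setdiff(seq_len(m), pairs[, 2])
  # nearest counterpart on the full, pre-removal matrix
  d_min <- if (length(unmatched) > 0) {
    apply(D[, unmatched, drop = FALSE], 2, min)
  } else numeric(0)
  list(pairs = pairs, distance = dist, unmatched = unmatched, d_min = d_min)
}

#' Greedily match the components of two multivariate series
#'
#' Partial matching step of SMETS: all cross distances between components of
#' the two series are computed, then the globally smallest remaining
#' distance is repeatedly selected, recorded, and both matched components
#' removed, until every component of the lower-dimensional series has
#' exactly one counterpart. Components of the larger series left unmatched
#' keep the smallest distance between themselves and any component of the
#' smaller series (measured on the full cross-distance matrix, before any
#' removals); these feed the entropy penalty.
#'
#' @param a,b Long tibbles each holding one multivariate series.
#' @param control A [smets_control()] bundle (distance backend settings).
#' @return An object of class `smets_match`: list with `pairs` (tibble
#'   `component_small`, `component_large`, `distance`), `unmatched` (tibble
#'   `component`, `d_min`), dimensions `n` (smaller) and `m` (larger), the
#'   series labels `smaller`/`larger`, and `swapped` (whether `b` was the
#'   smaller side).
#' @examples
#' a <- generate_toy_model("a", n_oscillating = 1, n_constant = 1, length = 32)
#' b <- generate_toy_model("b", n_oscillating = 1, n_constant = 3, length = 32)
#' greedy_match(a, b)
#' @export
greedy_match <- function(a, b, control = smets_control()) {
  check_ts_tbl(a)
  check_ts_tbl(b)
  la <- unique(a$series)
  lb <- unique(b$series)
  if (length(la) != 1 || length(lb) != 1) {
    abort("`a` and `b` must each contain exactly one series")
  }
  da <- dplyr::n_distinct(a$component)
  db <- dplyr::n_distinct(b$component)
  if (da < 1 || db < 1) abort("series must have at least one component")
  swapped <- db < da
  if (swapped) {
    tmp <- a; a <- b; b <- tmp
    tmp <- la; la <- lb; lb <- tmp
  }
  both <- dplyr::bind_rows(a, b)
  if (la == lb) abort("the two series must have distinct labels")
  reps <- wavelet_represent(both, control)
  comp_small <- sort(unique(a$component))
  comp_large <- sort(unique(b$component))
  D <- rep_cross_matrix(reps, la, lb, comp_small, comp_large)
  res <- greedy_match_matrix(D)
  structure(
    list(
      pairs = tibble::tibble(
        component_small = comp_small[res$pairs[, 1]],
        component_large = comp_large[res$pairs[, 2]],
        distance = res$distance),
      unmatched = tibble::tibble(
        component = comp_large[res$unmatched],
        d_min = res$d_min),
      n = length(comp_small), m = length(comp_large),
      smaller = la, larger = lb, swapped = swapped),
    class = "smets_match")
}

# cross-distance matrix between the components of two series inside one
# jointly-built representation object
rep_cross_matrix <- function(reps, la, lb, comp_a, comp_b) {
  pos <- sort(unique(reps$coef$index))
  if (length(pos) == 0) pos <- 1L
  M <- rep_densify(reps, pos)
  cross_dist(M[, paste(la, comp_a, sep = "\r"), drop = FALSE],
             M[, paste(lb, comp_b, sep = "\r"), drop = FALSE])
}

#' @export
print.smets_match <- function(x, ...) {
  cat(sprintf("SMETS partial matching: %s (n = %d) vs %s (m = %d)\n",
              x$smaller, x$n, x$larger, x$m))
  print(x$pairs, ...)
  if (nrow(x$unmatched) > 0) {
    cat("unmatched components of the larger series:\n")
    print(x$unmatched, ...)
  }
  invisible(x)
}

#' @method tidy smets_match
#' @export
tidy.smets_match <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component_small = x$pairs$component_small,
                   component_large = x$pairs$component_large,
                   distance = x$pairs$distance, matched = TRUE),
    tibble::tibble(component_small = NA_character_,
                   component_large = x$unmatched$component,
                   distance = x$unmatched$d_min, matched = FALSE))
}

#' Entropy penalty of the unmatched components
#'
#' Each unmatched component of the larger series contributes its distance to
#' the nearest component of the smaller series, weighted by its share of the
#' Shannon entropy among the unmatched components:
#' `EP = sum_j w_j d_j` with `w_j = H_j / sum_k H_k`. High-information
#' unmatched components therefore dominate the penalty, while constant
#' traces (zero entropy) contribute nothing; if all unmatched components are
#' constant — or nothing is unmatched — the penalty is zero.
#'
#' @param match A [greedy_match()] result.
#' @param entropies A [series_entropy()] table covering the unmatched
#'   components of the larger series.
#' @return A single non-negative number.
#' @export
entropy_penalty <- function(match, entropies) {
  if (!inherits(match, "smets_match")) abort("`match` must be a greedy_match() result")
  un <- match$unmatched
  if (nrow(un) == 0) return(0)
  ent <- entropies[entropies$series == match$larger, ]
  H <- ent$entropy[base::match(un$component, ent$component)]
  if (anyNA(H)) abort("`entropies` must cover every unmatched component")
  tot <- sum(H)
  if (tot == 0) return(0)
  sum(H / tot * un$d_min)
}

#' Dimension penalty between two multivariate series
#'
#' The ratio of the difference to the sum of the dimensions,
#' `P = (m - n) / (m + n)`, with `n <= m`. It is zero for equal dimensions,
#' strictly increasing in `m` for fixed `n`, and bounded below 1. It is what
#' separates series whose unmatched components carry no information (e.g.
#' extra constant variables), restoring the identity property of the
#' semi-metric.
#'
#' @param n Dimension of the smaller series (positive integer, vectorized).
#' @param m Dimension of the larger series, `m >= n`.
#' @return `(m - n) / (m + n)`.
#' @examples
#' dimension_penalty(3, 5)    # 0.25
#' dimension_penalty(3, 10)   # 7/13
#' @export
dimension_penalty <- function(n, m) {
  if (any(n < 1) || any(m < n)) abort("need m >= n >= 1")
  (m - n) / (m + n)
}

#' SMETS distance between two multivariate time series
#'
#' The Semi Metric Ensemble Time Series distance. Components of the
#' lower-dimensional series are greedily matched to their most similar
#' counterparts in the other series ([greedy_match()]); matched distances
#' `d` are aggregated as a p-norm with `p = n`, the smaller dimension
#' ([p_norm_distance()]); unmatched components add an entropy-weighted
#' nearest-counterpart penalty EP ([entropy_penalty()]) and the dimension
#' ratio P ([dimension_penalty()]). The two penalties are combined with a
#' 2-norm so that dimension differences do not dominate:
#'
#' \deqn{SMETS(A, B) = \|d\|_n + \sqrt{EP^2 + P^2}}
#'
#' The result is non-negative, symmetric, and zero exactly when the two
#' preprocessed series are identical; the triangle inequality holds when the
#' dimensions are equal (where SMETS reduces to the matched p-norm) but can
#' fail across dimensions, making SMETS a semi-metric.
#'
#' @param a,b Long tibbles each holding one multivariate series (see
#'   [as_ts_tbl()]); alternatively `a` may hold exactly two series and `b`
#'   be `NULL`.
#' @param control A [smets_control()] bundle.
#' @param details If `TRUE`, return a one-row tibble with the distance and
#'   its parts instead of a bare number.
#' @return A non-negative number, or a tibble with columns `series_a`,
#'   `series_b`, `smets`, `matched_pnorm`, `entropy_penalty`,
#'   `dimension_penalty`, `n`, `m` when `details = TRUE`.
#' @examples
#' a <- generate_toy_model("A", n_oscillating = 1, n_constant = 2, length = 64)
#' b <- generate_toy_model("B", n_oscillating = 1, n_constant = 4, length = 64)
#' smets_distance(a, b)                    # 0.25: pure dimension penalty
#' smets_distance(a, b, details = TRUE)
#' @export
smets_distance <- function(a, b = NULL, control = smets_control(),
                           details = FALSE) {
  if (is.null(b)) {
    check_ts_tbl(a)
    labs <- unique(a$series)
    if (length(labs) != 2) {
      abort("with `b = NULL`, `a` must contain exactly two series")
    }
    b <- dplyr::filter(a, .data$series == labs[2])
    a <- dplyr::filter(a, .data$series == labs[1])
  }
  mt <- greedy_match(a, b, control)
  norm_fun <- if (control$normalize) z_normalize else identity
  larger_data <- if (mt$swapped) a else b
  ent <- series_entropy(norm_fun(larger_data), bins = control$entropy_bins)
  pn <- p_norm_distance(mt$pairs$distance, p = mt$n)
  ep <- entropy_penalty(mt, ent)
  dp <- dimension_penalty(mt$n, mt$m)
  val <- pn + sqrt(ep^2 + dp^2)
  if (!details) return(val)
  tibble::tibble(
    series_a = unique(a$series), series_b = unique(b$series),
    smets = val, matched_pnorm = pn, entropy_penalty = ep,
    dimension_penalty = dp, n = mt$n, m = mt$m)
}
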