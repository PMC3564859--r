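#' Keep the k largest-magnitude coefficients of a transform
#'
#' Thins a full coefficient vector to its `k` entries of largest absolute
#' value, remembering their positions; all other positions are treated as
#' implicit zeros. Ties in magnitude are broken toward the lower transform
#' index so the representation is deterministic.
#'
#' @param coefficients Full numeric coefficient vector.
#' @param k Number of coefficients to retain (`1 <= k <= length(coefficients)`).
#' @return A tibble with columns `index` (strictly increasing positions in
#'   the full transform) and `coefficient`.
#' @examples
#' retain_top_k(c(3, -5, 0.1, 0.2), k = 2)
#' @export
retain_top_k <- function(coefficients, k) {
  if (length(k) != 1 || is.na(k) || k <= 0) abort("`k` must be a positive integer")
  k <- as.integer(k)
  if (k > length(coefficients)) {
    abort("`k` cannot exceed the number of coefficients")
  }
  keep <- sort(order(-abs(coefficients), seq_along(coefficients))[seq_len(k)])
  tibble::tibble(index = keep, coefficient = coefficients[keep])
}

#' Drop the padding-biased tail of a representation
#'
#' Trailing zero-padding of the input contaminates the trailing symbols of
#' the Haar representation (the finest-scale, latest-time coefficients), so
#' after retaining the top-k coefficients the representation is cut back by
#' removing retained symbols from the end, in transform-index order, down to
#' `target_len`. Under the default pipeline one symbol is removed (16 to
#' 15); heavier padding warrants removing more (e.g. 64 down to 47).
#'
#' @param rep A per-component representation tibble from [retain_top_k()],
#'   or a whole [wavelet_represent()] object (every component is truncated).
#' @param target_len Desired retained length, strictly smaller than the
#'   current one.
#' @return The truncated representation, same type as `rep`.
#' @export
truncate_padding_bias <- function(rep, target_len) {
  if (length(target_len) != 1 || target_len < 1) {
    abort("`target_len` must be a positive integer")
  }
  target_len <- as.integer(target_len)
  trunc_one <- function(tb) {
    if (target_len >= nrow(tb)) {
      abort("`target_len` must be smaller than the current retained length")
    }
    tb[order(tb$index)[seq_len(target_len)], , drop = FALSE]
  }
  if (inherits(rep, "smets_rep")) {
    parts <- split(rep$coef, interaction(rep$coef$series, rep$coef$component,
                                         drop = TRUE))
    rep$coef <- dplyr::arrange(dplyr::bind_rows(purrr::map(parts, trunc_one)),
                               .data$series, .data$component, .data$index)
    rep$settings$truncate_to <- target_len
    return(rep)
  }
  trunc_one(rep)
}

#' Build truncated Haar wavelet representations for a collection
#'
#' Runs the standard preprocessing pipeline on every component of every
#' series in `data`: optional z-normalization, zero-padding to a common
#' power-of-two length, orthonormal Haar transform, retention of the `k`
#' largest-magnitude coefficients, and removal of the padding-biased tail
#' symbols. With `wavelet = FALSE` in the control the "representation" is
#' the raw normalized, zero-padded series itself, so downstream distances
#' become plain Euclidean distances on the original traces.
#'
#' All series intended to be compared must be represented together (or with
#' an explicit common `pad_length`), because coefficient positions are only
#' comparable within one padded length.
#'
#' @param data A long tibble (see [as_ts_tbl()]).
#' @param control A [smets_control()] bundle.
#' @param pad_length Common padded length; default is the next power of two
#'   of the longest component in `data`.
#' @return An object of class `smets_rep`: a list with `coef` (tibble
#'   `series`, `component`, `index`, `coefficient`), `meta` (tibble `series`,
#'   `component`, `source_length`) and the effective pipeline `settings`.
#' @examples
#' d <- generate_toy_model("m", n_oscillating = 1, n_constant = 1, length = 32)
#' r <- wavelet_represent(d, smets_control(k = 8))
#' r$coef
#' @export
wavelet_represent <- function(data, control = smets_control(),
                              pad_length = NULL) {
  check_ts_tbl(data)
  if (!inherits(control, "smets_control")) abort("`control` must be smets_control()")
  if (control$normalize) data <- z_normalize(data)
  qs <- dplyr::summarise(dplyr::group_by(data, .data$series, .data$component),
                         source_length = dplyr::n(), .groups = "drop")
  Lmax <- max(qs$source_length)
  pad_length <- pad_length %||% next_power_of_two(Lmax)
  if (!is_power_of_two(pad_length) || pad_length < Lmax) {
    abort("`pad_length` must be a power of two no smaller than the longest component")
  }

  if (!control$wavelet) {
    coef <- dplyr::arrange(data, .data$series, .data$component, .data$time)
    coef <- dplyr::mutate(
      dplyr::group_by(coef, .data$series, .data$component),
      index = dplyr::row_number())
    coef <- dplyr::ungroup(coef)
    out_coef <- tibble::tibble(series = coef$series, component = coef$component,
                               index = coef$index, coefficient = coef$value)
    settings <- list(normalize = control$normalize, wavelet = FALSE,
                     k = pad_length, truncate_to = pad_length,
                     pad_length = pad_length)
    return(structure(list(coef = out_coef, meta = qs, settings = settings),
                     class = "smets_rep"))
  }

  k_eff <- min(control$k, pad_length)
  t_eff <- control$truncate_to %||% max(k_eff - 1L, 1L)
  t_eff <- min(t_eff, k_eff)

  mats <- ts_split(data)
  rows <- purrr::imap(mats, function(m, sname) {
    purrr::map(colnames(m), function(cn) {
      x <- c(m[, cn], numeric(pad_length - nrow(m)))
      tb <- retain_top_k(haar_dwt(x), k_eff)
      if (t_eff < nrow(tb)) tb <- truncate_padding_bias(tb, t_eff)
      tibble::tibble(series = sname, component = cn,
                     index = tb$index, coefficient = tb$coefficient)
    }) |> dplyr::bind_rows()
  })
  out_coef <- dplyr::arrange(dplyr::bind_rows(rows),
                             .data$series, .data$component, .data$index)
  settings <- list(normalize = control$normalize, wavelet = TRUE,
                   k = k_eff, truncate_to = t_eff, pad_length = pad_length)
  structure(list(coef = out_coef, meta = qs, settings = settings),
            class = "smets_rep")
}

#' @export
print.smets_rep <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Haar representation: %d series, %d components (pad %d, k %d, keep %d)\n",
    dplyr::n_distinct(x$meta$series), nrow(x$meta),
    s$pad_length, s$k, s$truncate_to))
  print(x$coef, ...)
  invisible(x)
}

# densify retained coefficients of one smets_rep over the given positions;
# returns a positions x components matrix, columns keyed "series\rcomponent"
rep_densify <- function(rep, positions) {
  key <- paste(rep$coef$series, rep$coef$component, sep = "\r")
  all_key <- paste(rep$meta$series, rep$meta$component, sep = "\r")
  m <- matrix(0, nrow = length(positions), ncol = length(all_key),
              dimnames = list(NULL, all_key))
  ridx <- match(rep$coef$index, positions)
  cidx <- match(key, all_key)
  m[cbind(ridx, cidx)] <- rep$coef$coefficient
  m
}

# Euclidean cross-distance matrix between the columns of two matrices.
# Differences are formed explicitly (not via the crossprod expansion) so
# identical columns give exactly zero.
cross_dist <- function(A, B) {
  out <- matrix(0, ncol(A), ncol(B))
  for (j in seq_len(ncol(B))) {
    out[, j] <- sqrt(colSums((A - B[, j])^2))
  }
  out
}

#' Euclidean distance between wavelet representations
#'
#' Distances are computed over the union of retained coefficient positions,
#' with positions absent from one side contributing implicit zeros: the
#' distance is exactly the Euclidean distance between the two zero-filled
#' coefficient vectors, so it inherits every metric property (symmetry,
#' identity on retained content, triangle inequality). Representations
#' built with different pipeline settings are not comparable and raise an
#' error.
#'
#' When the two sides retain the same positions — always the case at
#' `k = all`, and for identical or near-identical traces — zero-filling is
#' an orthogonal projection and the distance is a lower bound on the
#' Euclidean distance between the padded series. When the retained position
#' sets differ the bound can be exceeded by a margin controlled by the
#' discarded magnitudes; see the methods vignette for why no distance on
#' standalone top-k representations can be both a metric and a universal
#' lower bound.
#'
#' @param a,b `smets_rep` objects (typically one series each, possibly many
#'   components).
#' @return A tibble of all cross pairs: `series_a`, `component_a`,
#'   `series_b`, `component_b`, `distance`.
#' @export
representation_distance <- function(a, b) {
  if (!inherits(a, "smets_rep") || !inherits(b, "smets_rep")) {
    abort("both arguments must be wavelet_represent() objects")
  }
  if (!identical(a$settings, b$settings)) {
    abort("representations were built with mismatched pipeline settings")
  }
  pos <- sort(unique(c(a$coef$index, b$coef$index)))
  if (length(pos) == 0) pos <- 1L
  A <- rep_densify(a, pos)
  B <- rep_densify(b, pos)
  D <- cross_dist(A, B)
  ka <- strsplit(colnames(A), "\r", fixed = TRUE)
  kb <- strsplit(colnames(B), "\r", fixed = TRUE)
  grid <- expand.grid(ia = seq_along(ka), ib = seq_along(kb))
  tibble::tibble(
    series_a = purrr::map_chr(ka[grid$ia], 1),
    component_a = purrr::map_chr(ka[grid$ia], 2),
    series_b = purrr::map_chr(kb[grid$ib], 1),
    component_b = purrr::map_chr(kb[grid$ib], 2),
    distance = D[cbind(grid$ia, grid$ib)]
  )
}
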