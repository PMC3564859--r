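#' Pairwise SMETS distances over a collection of multivariate series
#'
#' Computes the full symmetric SMETS distance matrix between every pair of
#' series in `data`, sharing one preprocessing pass (normalization, common
#' padded length, wavelet representations) across the collection so all
#' pairs are compared in the same representation space.
#'
#' @param data A long tibble holding at least two series (see
#'   [as_ts_tbl()]).
#' @param control A [smets_control()] bundle.
#' @return An object of class `smets_dist`: list with `labels`, the
#'   symmetric `matrix` (zero diagonal), a `pairs` tibble with the per-pair
#'   breakdown (matched p-norm, entropy penalty, dimension penalty,
#'   dimensions), the `control` used, and `method = "smets"`.
#' @seealso [smets_hclust()], [tidy.smets_dist()], [autoplot.smets_dist()]
#' @examples
#' specs <- tibble::tibble(name = c("A", "B", "C"),
#'                         n_constant = c(2, 4, 9))
#' trio <- generate_toy_collection(specs, n_oscillating = 1, length = 64)
#' fit <- smets(trio)
#' as.matrix(fit)
#' @export
smets <- function(data, control = smets_control()) {
  check_ts_tbl(data)
  labels <- unique(data$series)
  if (length(labels) < 2) abort("need at least two series")

  norm <- if (control$normalize) z_normalize(data) else data
  reps <- wavelet_represent(norm,
                            smets_control(normalize = FALSE,
                                          wavelet = control$wavelet,
                                          k = control$k,
                                          truncate_to = control$truncate_to))
  ent <- series_entropy(norm, bins = control$entropy_bins)

  pos <- sort(unique(reps$coef$index))
  if (length(pos) == 0) pos <- 1L
  M <- rep_densify(reps, pos)
  comp_of <- lapply(labels, function(l) sort(unique(data$component[data$series == l])))
  names(comp_of) <- labels

  one_pair <- function(la, lb) {
    ca <- comp_of[[la]]
    cb <- comp_of[[lb]]
    swapped <- length(cb) < length(ca)
    if (swapped) {
      tmp <- la; la2 <- lb; lb2 <- tmp
      tmp <- ca; ca <- cb; cb <- tmp
    } else {
      la2 <- la; lb2 <- lb
    }
    D <- cross_dist(M[, paste(la2, ca, sep = "\r"), drop = FALSE],
                    M[, paste(lb2, cb, sep = "\r"), drop = FALSE])
    res <- greedy_match_matrix(D)
    n <- length(ca)
    m <- length(cb)
    pn <- p_norm_distance(res$distance, p = n)
    ent_l <- ent[ent$series == lb2, ]
    H <- ent_l$entropy[base::match(cb[res$unmatched], ent_l$component)]
    ep <- if (length(H) == 0 || sum(H) == 0) 0 else sum(H / sum(H) * res$d_min)
    dp <- dimension_penalty(n, m)
    tibble::tibble(matched_pnorm = pn, entropy_penalty = ep,
                   dimension_penalty = dp, smets = pn + sqrt(ep^2 + dp^2),
                   n = n, m = m)
  }

  idx <- which(upper.tri(matrix(0, length(labels), length(labels))), arr.ind = TRUE)
  rows <- purrr::map2(labels[idx[, 1]], labels[idx[, 2]], one_pair)
  pairs <- dplyr::bind_cols(
    tibble::tibble(series_a = labels[idx[, 1]], series_b = labels[idx[, 2]]),
    dplyr::bind_rows(rows))

  mat <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  mat[cbind(pairs$series_a, pairs$series_b)] <- pairs$smets
  mat[cbind(pairs$series_b, pairs$series_a)] <- pairs$smets

  structure(list(labels = labels, matrix = mat, pairs = pairs,
                 control = control, method = "smets"),
            class = "smets_dist")
}

#' Baseline comparator: distances between component averages
#'
#' The traditional way to compare groups of time series of unequal
#' dimension is to reduce each group to its (weighted) average trace and
#' compare those univariate averages. This comparator is provided as the
#' trivial baseline: Euclidean distances between the per-series averages of
#' [average_baseline()].
#'
#' @inheritParams smets
#' @param weights Optional component weights, see [average_baseline()].
#' @return A `smets_dist` object with `method = "average"`.
#' @export
baseline_distance_matrix <- function(data, control = smets_control(),
                                     weights = NULL) {
  check_ts_tbl(data)
  labels <- unique(data$series)
  if (length(labels) < 2) abort("need at least two series")
  avg <- average_baseline(if (control$normalize) z_normalize(data) else data,
                          weights = weights)
  mats <- ts_split(avg)
  qs <- vapply(mats, nrow, integer(1))
  L <- max(qs)
  V <- vapply(labels, function(l) c(mats[[l]][, 1], numeric(L - qs[[l]])),
              numeric(L))
  mat <- as.matrix(stats::dist(t(V)))
  dimnames(mat) <- list(labels, labels)
  structure(list(labels = labels, matrix = mat, pairs = NULL,
                 control = control, method = "average"),
            class = "smets_dist")
}

#' Pointwise (weighted) average of the components of each series
#'
#' @param data A long tibble (see [as_ts_tbl()]).
#' @param weights Optional numeric weights, one per component of each
#'   series, either named by component or given in component (alphabetical)
#'   order; they are normalized to sum to one. `NULL` means equal weights.
#' @return A long tibble with one component `"average"` per series.
#' @export
average_baseline <- function(data, weights = NULL) {
  check_ts_tbl(data)
  mats <- ts_split(data)
  rows <- purrr::imap(mats, function(m, sname) {
    w <- if (is.null(weights)) rep(1, ncol(m)) else weights
    if (!is.null(names(w)) && any(nzchar(names(w)))) {
      w <- w[colnames(m)]
      if (anyNA(w)) abort(sprintf("weights missing for components of %s", sname))
    }
    if (length(w) != ncol(m)) {
      abort(sprintf("series %s has %d components but %d weights",
                    sname, ncol(m), length(w)))
    }
    if (sum(w) == 0) abort("weights must not sum to zero")
    tms <- sort(unique(data$time[data$series == sname]))
    tibble::tibble(series = sname, component = "average",
                   time = tms[seq_len(nrow(m))],
                   value = as.numeric(m %*% (w / sum(w))))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.smets_dist <- function(x, ...) {
  cat(sprintf("%s distance matrix over %d series\n",
              if (x$method == "smets") "SMETS" else "Average-baseline",
              length(x$labels)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' @export
as.matrix.smets_dist <- function(x, ...) x$matrix

#' @export
as.dist.smets_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$matrix, diag = diag, upper = upper)
}

#' Tidy the pairwise distances of a fitted distance matrix
#'
#' @param x A [smets()] or [baseline_distance_matrix()] result.
#' @param ... Unused.
#' @return One row per unordered series pair; for SMETS fits the penalty
#'   breakdown columns are included.
#' @method tidy smets_dist
#' @export
tidy.smets_dist <- function(x, ...) {
  if (!is.null(x$pairs)) return(x$pairs)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(series_a = x$labels[idx[, 1]],
                 series_b = x$labels[idx[, 2]],
                 distance = x$matrix[idx])
}

#' One-row summary of a fitted distance matrix
#'
#' @inheritParams tidy.smets_dist
#' @return A one-row tibble: number of series, dimension range, distance
#'   range, and the pipeline settings.
#' @method glance smets_dist
#' @export
glance.smets_dist <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  tibble::tibble(
    n_series = length(x$labels),
    min_distance = min(off), max_distance = max(off),
    method = x$method,
    wavelet = x$control$wavelet, k = x$control$k,
    entropy_bins = x$control$entropy_bins, linkage = x$control$linkage)
}

#' Heat map of a distance matrix
#'
#' @param object A `smets_dist` object.
#' @param ... Unused.
#' @return A ggplot: grayscale heat map of the pairwise distances.
#' @method autoplot smets_dist
#' @export
autoplot.smets_dist <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$matrix, rownames = "series_a"),
    -"series_a", names_to = "series_b", values_to = "distance")
  df$series_a <- factor(df$series_a, levels = object$labels)
  df$series_b <- factor(df$series_b, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$series_a, y = .data$series_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal()
}

#' Line plot of component traces over time
#'
#' Convenience plot of a collection in the canonical long layout, one facet
#' per series.
#'
#' @param data A long tibble (see [as_ts_tbl()]).
#' @return A ggplot.
#' @export
plot_series <- function(data) {
  check_ts_tbl(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' @param x A `smets_dist` object.
#' @param method Linkage criterion; defaults to the one recorded in the
#'   fit's control (`"average"` unless changed).
#' @return An [stats::hclust] tree with the series labels.
#' @examples
#' \donttest{
#' specs <- tibble::tibble(name = c("A", "B", "C"), n_constant = c(2, 4, 9))
#' fit <- smets(generate_toy_collection(specs, n_oscillating = 1, length = 64))
#' smets_hclust(fit)$merge
#' }
#' @export
smets_hclust <- function(x, method = NULL) {
  if (!inherits(x, "smets_dist")) abort("`x` must be a smets()/baseline fit")
  if (any(is.na(x$matrix))) abort("distance matrix contains NaN")
  method <- method %||% x$control$linkage
  stats::hclust(stats::as.dist(x$matrix), method = method)
}

#' Export a clustering as Newick text
#'
#' @param hc An [stats::hclust] tree (from [smets_hclust()]).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to `path`.
#' @export
smets_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the 'ape' package")
  }
  txt <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Merge table of a clustering
#'
#' @param hc An [stats::hclust] tree.
#' @return A tibble with one row per agglomeration step: the two merged
#'   nodes (negative numbers are leaves, positive earlier steps) and the
#'   merge height.
#' @export
merge_table <- function(hc) {
  tibble::tibble(step = seq_len(nrow(hc$merge)),
                 left = hc$merge[, 1], right = hc$merge[, 2],
                 height = hc$height)
}

#' Write a distance matrix as CSV with labels
#'
#' @param x A `smets_dist` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(x, path) {
  df <- tibble::as_tibble(x$matrix, rownames = "series")
  readr::write_csv(df, path)
  invisible(path)
}
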