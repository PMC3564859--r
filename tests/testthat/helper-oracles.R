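# Independent oracles and random-instance generators shared across tests.

# Greedy partial matching by a different route: sort all (distance, i, j)
# edges once, then sweep, accepting an edge when neither endpoint is used.
# Equivalent to repeated global-minimum selection with lexicographic
# tie-breaking, but implemented without rescanning the matrix.
oracle_greedy <- function(D) {
  n <- nrow(D)
  m <- ncol(D)
  edges <- expand.grid(i = seq_len(n), j = seq_len(m))
  edges$d <- D[cbind(edges$i, edges$j)]
  edges <- edges[order(edges$d, edges$i, edges$j), ]
  used_i <- logical(n)
  used_j <- logical(m)
  pairs <- matrix(0L, nrow = n, ncol = 2)
  dist <- numeric(n)
  k <- 0L
  for (r in seq_len(nrow(edges))) {
    e <- edges[r, ]
    if (used_i[e$i] || used_j[e$j]) next
    k <- k + 1L
    pairs[k, ] <- c(e$i, e$j)
    dist[k] <- e$d
    used_i[e$i] <- TRUE
    used_j[e$j] <- TRUE
    if (k == n) break
  }
  unmatched <- which(!used_j)
  d_min <- if (length(unmatched) > 0) {
    apply(D[, unmatched, drop = FALSE], 2, min)
  } else numeric(0)
  list(pairs = pairs, distance = dist, unmatched = unmatched, d_min = d_min)
}

# random multivariate series in the canonical long layout, mixing the
# behavior classes the method is meant to discriminate
rand_series <- function(name, dim, q) {
  vals <- lapply(seq_len(dim), function(i) {
    switch(sample(4, 1),
           cumsum(rnorm(q)),                                  # random walk
           sin(2 * pi * seq_len(q) / sample(4:(q / 2), 1)) +
             rnorm(q, sd = 0.2),                              # noisy oscillator
           exp(-runif(1, 0.01, 0.3) * seq_len(q)) + rnorm(q, sd = 0.05),
           rep(runif(1, -3, 3), q))                           # constant
  })
  tibble::tibble(
    series = name,
    component = rep(sprintf("v%02d", seq_len(dim)), each = q),
    time = rep(seq_len(q) - 1, times = dim),
    value = unlist(vals))
}

relabel_series <- function(data, name) {
  data$series <- name
  data
}

# two-pass mean/population-variance normalization, independent of znorm_vec
oracle_znorm <- function(x) {
  mu <- sum(x) / length(x)
  v <- sum((x - mu)^2) / length(x)
  if (v == 0) rep(0, length(x)) else (x - mu) / sqrt(v)
}

# Euclidean distance between two raw series zero-padded to a common length
raw_padded_dist <- function(x, y, L) {
  sqrt(sum((c(x, numeric(L - length(x))) - c(y, numeric(L - length(y))))^2))
}

# view of one series inside a jointly-built representation object
rep_subset <- function(reps, name) {
  structure(list(coef = reps$coef[reps$coef$series == name, ],
                 meta = reps$meta[reps$meta$series == name, ],
                 settings = reps$settings),
            class = "smets_rep")
}
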