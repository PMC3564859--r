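test_that("Haar transform matches hand-computed and frozen oracle values", {
  expect_identical(haar_dwt(rep(0, 4)), rep(0, 4))
  # recursive average/difference with 1/sqrt(2) factors, by hand
  expect_equal(haar_dwt(c(1, 1, 1, 1)), c(2, 0, 0, 0))
  # frozen from an independent reference implementation of the orthonormal
  # Haar DWT applied to 1:8
  expect_equal(haar_dwt(as.numeric(1:8)),
               c(12.727922061358, -5.656854249492, -2, -2,
                 -1 / sqrt(2), -1 / sqrt(2), -1 / sqrt(2), -1 / sqrt(2)),
               tolerance = 1e-9)
})

test_that("Haar transform conserves energy and inverts exactly", {
  set.seed(21)
  for (L in c(2, 16, 64)) {
    x <- rnorm(L)
    w <- haar_dwt(x)
    expect_equal(sum(w^2), sum(x^2), tolerance = 1e-9)
    expect_equal(inv_haar_dwt(w), x, tolerance = 1e-9)
  }
})

test_that("non-power-of-two input is rejected with a pointer to padding", {
  expect_error(haar_dwt(rnorm(6)), "pad_to_power_of_two")
})

test_that("retain_top_k keeps the largest magnitudes, ties to lower index", {
  full <- retain_top_k(c(3, -5, 0.1, 0.2), k = 4)
  expect_equal(full$index, 1:4)
  top2 <- retain_top_k(c(3, -5, 0.1, 0.2), k = 2)
  expect_equal(top2$index, c(1, 2))
  expect_equal(top2$coefficient, c(3, -5))
  # sort-by-magnitude oracle on a random vector
  set.seed(3)
  w <- rnorm(32)
  k <- 7
  keep <- sort(order(-abs(w))[1:k])
  expect_equal(retain_top_k(w, k)$index, keep)
  # magnitude tie: equal values keep the earlier position
  tie <- retain_top_k(c(1, -2, 2, 0), k = 1)
  expect_equal(tie$index, 2)
  expect_error(retain_top_k(w, 0), "positive")
  expect_error(retain_top_k(w, 33), "exceed")
})

test_that("padding-bias truncation drops trailing retained symbols", {
  tb <- retain_top_k(c(9, 1, 8, 2, 7, 3, 6, 5), k = 4)   # indices 1,3,5,7
  cut <- truncate_padding_bias(tb, 3)
  expect_equal(cut$index, c(1, 3, 5))
  expect_error(truncate_padding_bias(tb, 4), "smaller")
  expect_error(truncate_padding_bias(tb, 9), "smaller")
})

test_that("the default pipeline retains 16 then truncates to 15 symbols", {
  q <- 234
  d <- as_ts_tbl(data.frame(time = seq_len(q) - 1, x = rnorm(q)))
  r <- wavelet_represent(d, smets_control())
  expect_equal(r$settings$pad_length, 256)
  expect_equal(r$settings$k, 16)
  expect_equal(nrow(r$coef), 15)
  # the dropped symbol is the retained coefficient of largest transform index
  r16 <- wavelet_represent(d, smets_control(truncate_to = 16))
  expect_equal(setdiff(r16$coef$index, r$coef$index), max(r16$coef$index))
})

test_that("deeper truncation reproduces the long-series setting (64 -> 47)", {
  q <- 6000
  d <- as_ts_tbl(data.frame(time = seq_len(q) - 1, x = rnorm(q)))
  r <- wavelet_represent(d, smets_control(k = 64, truncate_to = 47))
  expect_equal(r$settings$pad_length, 8192)
  expect_equal(nrow(r$coef), 47)
})

test_that("representation distances use the union of retained positions", {
  # densified 3-4-5 example: one side holds 3 at a position the other lacks,
  # the other holds 4 at a second position; absent positions are implicit
  # zeros
  mk <- function(series, idx, coefs, settings) {
    structure(list(
      coef = tibble::tibble(series = series, component = "v",
                            index = idx, coefficient = coefs),
      meta = tibble::tibble(series = series, component = "v",
                            source_length = 4L),
      settings = settings), class = "smets_rep")
  }
  s <- list(normalize = TRUE, wavelet = TRUE, k = 2L, truncate_to = 2L,
            pad_length = 4L)
  a <- mk("a", 1L, 3, s)
  b <- mk("b", 2L, 4, s)
  expect_equal(representation_distance(a, b)$distance, 5)
  expect_equal(representation_distance(a, a)$distance, 0)
  s2 <- s
  s2$k <- 3L
  expect_error(representation_distance(a, mk("c", 2L, 4, s2)), "mismatched")
})

test_that("keeping every coefficient reproduces the raw Euclidean distance", {
  set.seed(9)
  q <- 48
  L <- 64
  d <- dplyr::bind_rows(rand_series("a", 2, q), rand_series("b", 2, q))
  dn <- z_normalize(d)
  ctl <- smets_control(normalize = FALSE, k = L, truncate_to = L)
  reps <- wavelet_represent(dn, ctl)
  got <- representation_distance(rep_subset(reps, "a"), rep_subset(reps, "b"))
  mats <- split(dn$value, paste(dn$series, dn$component))
  for (r in seq_len(nrow(got))) {
    x <- mats[[paste("a", got$component_a[r])]]
    y <- mats[[paste("b", got$component_b[r])]]
    expect_equal(got$distance[r], raw_padded_dist(x, y, L), tolerance = 1e-9)
  }
})

test_that("distances equal the Euclidean distance between densified vectors", {
  # the union-with-zeros convention is an embedding: the distance must match
  # a by-hand zero-fill of both coefficient sets over the full transform
  set.seed(33)
  for (rep_i in 1:25) {
    q <- sample(16:128, 1)
    L <- 2^ceiling(log2(q))
    d <- dplyr::bind_rows(
      tibble::tibble(series = "a", component = "v", time = seq_len(q),
                     value = oracle_znorm(cumsum(rnorm(q)))),
      tibble::tibble(series = "b", component = "v", time = seq_len(q),
                     value = oracle_znorm(cumsum(rnorm(q)))))
    k <- sample(c(4, 8, 16), 1)
    reps <- wavelet_represent(d, smets_control(normalize = FALSE, k = k))
    got <- representation_distance(rep_subset(reps, "a"),
                                   rep_subset(reps, "b"))$distance
    dense <- function(name) {
      v <- numeric(L)
      cf <- reps$coef[reps$coef$series == name, ]
      v[cf$index] <- cf$coefficient
      v
    }
    expect_equal(got, sqrt(sum((dense("a") - dense("b"))^2)), tolerance = 1e-9)
  }
})

test_that("coinciding retained positions lower-bound the raw distance", {
  # zero-filling is an orthogonal projection whenever both sides kept the
  # same positions (always true at k = all), and projections only shrink
  # Euclidean distances
  set.seed(34)
  checked <- 0
  for (rep_i in 1:200) {
    q <- sample(16:64, 1)
    L <- 2^ceiling(log2(q))
    xn <- oracle_znorm(cumsum(rnorm(q)))
    yn <- oracle_znorm(cumsum(rnorm(q)))
    d <- dplyr::bind_rows(
      tibble::tibble(series = "a", component = "v", time = seq_len(q), value = xn),
      tibble::tibble(series = "b", component = "v", time = seq_len(q), value = yn))
    raw <- raw_padded_dist(xn, yn, L)
    for (k in c(4, 16, L)) {
      reps <- wavelet_represent(d, smets_control(normalize = FALSE, k = k))
      idx_a <- reps$coef$index[reps$coef$series == "a"]
      idx_b <- reps$coef$index[reps$coef$series == "b"]
      if (!identical(idx_a, idx_b)) next
      checked <- checked + 1
      expect_lte(representation_distance(rep_subset(reps, "a"),
                                         rep_subset(reps, "b"))$distance,
                 raw + 1e-9)
    }
  }
  expect_gte(checked, 200)   # k = all always qualifies
})

test_that("disabling the wavelet backend yields raw-series distances", {
  set.seed(2)
  q <- 30
  d <- dplyr::bind_rows(rand_series("a", 1, q), rand_series("b", 1, q))
  dn <- z_normalize(d)
  val <- smets_distance(dplyr::filter(dn, series == "a"),
                        dplyr::filter(dn, series == "b"),
                        smets_control(normalize = FALSE, wavelet = FALSE))
  expect_equal(val,
               raw_padded_dist(dn$value[dn$series == "a"],
                               dn$value[dn$series == "b"], 32),
               tolerance = 1e-9)
})
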