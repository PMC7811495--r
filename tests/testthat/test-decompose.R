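# matrix building, t-PCA/Promax, selection, back-projection

test_that("build_matrix stacks rows and windows columns as documented", {
  obj <- small_sim(n = 4L, snr = 10, seed = 3L)
  Z <- build_matrix(obj$sim$data, c(0, 800))     # right-open window
  expect_equal(dim(Z$Z), c(4L * 65L, 120L))
  Zf <- build_matrix(obj$sim$data)
  expect_equal(dim(Zf$Z), c(260L, 151L))
  # row_index round trip: row k -> (s, c, ch) -> row k
  for (k in c(1L, 66L, 200L)) {
    ri <- Zf$row_index[k, ]
    expect_equal(unname(unlist(
      Zf$row_index[Zf$row_index$subject == ri$subject &
                   Zf$row_index$condition == ri$condition &
                   Zf$row_index$channel == ri$channel, ])),
      unname(unlist(ri)))
    expect_equal(Zf$Z[k, ],
                 obj$sim$data$data[ri$subject, ri$condition, ri$channel, ])
  }
})

test_that("retained-count rule is inclusive at exact threshold equality", {
  expect_equal(retained_count(c(4, 3, 2, 1), 0.99), 4L)
  expect_equal(retained_count(c(4, 3, 2, 1), 0.70), 2L)   # 7/10 inclusive
  expect_equal(retained_count(c(4, 3, 2, 1), 0.40), 1L)
})

test_that("noiseless rank-2 data give R = 2 and exact reconstruction", {
  set.seed(8)
  times <- default_times()
  n_t <- length(times)
  u <- matrix(rnorm(40), 20)                    # 20 rows, 2 factors
  w <- rbind(sin(seq(0, 3, length.out = n_t)), cos(seq(0, 5, length.out = n_t)))
  arr <- array(0, c(5L, 1L, 4L, n_t))
  row <- 1L
  for (s in 1:5) for (ch in 1:4) {
    arr[s, 1, ch, ] <- u[row, ] %*% w + 0.3    # constant offset
    row <- row + 1L
  }
  ds <- erp_dataset(arr, times, 150, c("Fz", "FCz", "Cz", "Pz"))
  dec <- tpca(build_matrix(ds), 0.99)
  expect_equal(dec$R, 2L)
  bp <- back_project(dec, seq_len(dec$R))
  expect_lt(max(abs(bp$data - arr)) / max(abs(arr)), 1e-8)
  expect_equal(sum(dec$explained_variance_pct), 100, tolerance = 1e-6)
  # eigenvalues are non-increasing and non-negative
  expect_true(all(diff(dec$eigenvalues) <= 1e-10))
  expect_true(all(dec$eigenvalues >= -1e-12))
  # unrotated loadings have orthonormal columns
  expect_equal(crossprod(dec$loadings_unrotated), diag(2), tolerance = 1e-10)
})

test_that("full back-projection reproduces the input on real-shaped data", {
  obj <- small_sim(n = 8L, snr = 10, seed = 3L)
  filt <- wavelet_filter(obj$sim$data)
  expect_warning(dec <- tpca(build_matrix(filt), 1.0), "rank-deficient")
  bp <- back_project(dec, seq_len(dec$R))
  expect_lt(max(abs(bp$data - filt$data)) / max(abs(filt$data)), 1e-8)
})

test_that("scores times pattern reproduces the retained projection", {
  obj <- small_sim(n = 6L, snr = 10, seed = 3L)
  Z <- build_matrix(obj$sim$data)
  dec <- tpca(Z, 0.99)
  Zc <- sweep(Z$Z, 2, Z$column_means)
  V <- dec$loadings_unrotated
  proj <- Zc %*% V %*% t(V)
  expect_lt(max(abs(dec$scores %*% t(dec$loadings) - proj)) /
              max(abs(proj)), 1e-8)
  # oblique consistency: pattern Phi pattern' equals the retained
  # covariance contribution
  lhs <- dec$loadings %*% dec$factor_correlation %*% t(dec$loadings)
  lam <- dec$eigenvalues[seq_len(dec$R)]
  rhs <- V %*% diag(lam, dec$R) %*% t(V)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
})

test_that("back-projection is sign-invariant and scale-equivariant", {
  obj <- small_sim(n = 6L, snr = 10, seed = 3L)
  filt <- wavelet_filter(obj$sim$data)
  dec <- tpca(build_matrix(filt), 0.99)
  S <- c(1L, 2L)
  bp <- back_project(dec, S)
  flipped <- dec
  flipped$loadings[, 2L] <- -flipped$loadings[, 2L]
  flipped$scores[, 2L] <- -flipped$scores[, 2L]
  expect_equal(back_project(flipped, S)$data, bp$data, tolerance = 1e-12)
  # scale the input by c -> back-projection scales by c
  scaled <- filt
  scaled$data <- filt$data * 2.5
  dec2 <- tpca(build_matrix(scaled), 0.99)
  bp2 <- back_project(dec2, S)
  expect_lt(max(abs(bp2$data - 2.5 * bp$data)) / max(abs(bp2$data)), 1e-6)
  expect_error(back_project(dec, integer(0)), "empty")
})

test_that("spatial similarity matches the hand-computed Pearson oracle", {
  topo <- rbind(c(1, 2, 3), c(1, 2, 4), c(3, 1, 2))
  r12 <- 9 / sqrt(84)         # hand evaluation of the Pearson formula
  r13 <- cor(topo[1, ], topo[3, ])
  r23 <- cor(topo[2, ], topo[3, ])
  got <- spatial_similarity(topo)
  expect_equal(got$mean, mean(c(r12, r13, r23)), tolerance = 1e-12)
  expect_equal(got$sd, sd(c(r12, r13, r23)), tolerance = 1e-12)
  expect_equal(got$n_pairs, 3L)
  # identical topographies -> 1 +/- 0
  same <- spatial_similarity(matrix(rep(c(2, 5, 1, 4), 4), 4, byrow = TRUE))
  expect_equal(same$mean, 1)
  expect_equal(same$sd, 0)
  # half t, half -t: mean over pairs = (same - opposite) / total
  t6 <- c(1, 4, 2, 6, 3, 5)
  mix <- rbind(t6, t6, -t6, -t6)
  got2 <- spatial_similarity(mix)
  expect_equal(got2$mean, (2 - 4) / 6, tolerance = 1e-12)
})

test_that("component selection finds N2/FCz and P3/Cz and supports override", {
  obj <- small_sim(n = 12L, snr = 10, seed = 3L)
  filt <- wavelet_filter(obj$sim$data)
  dec <- tpca(build_matrix(filt), 0.99, min_components = 12L)
  selN2 <- select_components(dec, n2_criteria())
  selP3 <- select_components(dec, p3_criteria())
  expect_gt(length(selN2$selected), 0L)
  expect_gt(length(selP3$selected), 0L)
  expect_length(intersect(selN2$selected, selP3$selected), 0L)
  expect_true(all(selN2$detail$peak_ms[selN2$selected] >= 260 &
                  selN2$detail$peak_ms[selN2$selected] <= 400))
  # a sign flip of a selected component does not change its selection
  flip <- selN2$selected[1L]
  dec2 <- dec
  dec2$loadings[, flip] <- -dec2$loadings[, flip]
  dec2$scores[, flip] <- -dec2$scores[, flip]
  sel2 <- select_components(dec2, n2_criteria())
  expect_true(flip %in% sel2$selected)
  # impossible criteria -> empty selection with a warning
  expect_warning(
    none <- select_components(dec, selection_criteria(-1, c(700, 790),
                                                      "T8", 0.99)),
    "no components")
  expect_length(none$selected, 0L)
  # manual override is honoured and logged
  man <- select_components(dec, n2_criteria(), manual = c(1L, 2L))
  expect_equal(man$selected, c(1L, 2L))
  expect_true(man$manual)
})
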