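# wavelet band filter, epoch rejection, baseline correction, averaging,
# resampling

test_that("constructed 6.8 filters satisfy the defining identities", {
  for (nm in c("bior6.8", "rbio6.8")) {
    fb <- wavelet_filters(nm)
    # lengths and DC gain of the canonical 11/17-tap pair
    lens <- sort(c(length(fb$dec_lo$v), length(fb$rec_lo$v)))
    expect_equal(lens, c(11L, 17L))
    expect_equal(sum(fb$dec_lo$v) * sum(fb$rec_lo$v), 2, tolerance = 1e-12)
    # half-band product: even taps vanish except the centre
    p <- convolve(fb$dec_lo$v, rev(fb$rec_lo$v), type = "open")
    t0 <- fb$dec_lo$t0 + fb$rec_lo$t0
    idx <- t0:(t0 + length(p) - 1L)
    even <- p[idx %% 2L == 0L]
    expect_equal(even[idx[idx %% 2L == 0L] == 0L], 1, tolerance = 1e-12)
    expect_lt(max(abs(even[idx[idx %% 2L == 0L] != 0L])), 1e-12)
    # vanishing moments: the highpass side annihilates polynomials
    hp <- fb$dec_hi$v
    n <- fb$dec_hi$t0 + seq_along(hp) - 1L
    for (k in 0:5) expect_lt(abs(sum(hp * n^k)), 1e-8)
  }
  expect_error(wavelet_filters("db4"), "unknown mother wavelet")
})

test_that("keeping every level reconstructs the input (PR identity)", {
  set.seed(1)
  x <- rnorm(151)
  sp <- wavelet_filter_spec(keep_detail_levels = 1:8, keep_approx = TRUE)
  expect_lt(max(abs(wavelet_filter(x, sp) - x)) / max(abs(x)), 1e-8)
  # also with zero-extension boundary handling and for bior orientation
  sp0 <- wavelet_filter_spec(mother = "bior6.8", keep_detail_levels = 1:8,
                             keep_approx = TRUE, boundary = "zero")
  expect_lt(max(abs(wavelet_filter(x, sp0) - x)) / max(abs(x)), 1e-8)
})

test_that("band filter passes 3 Hz and rejects 20 Hz per the dyadic bands", {
  # dyadic oracle at fs = 150: level-j detail spans fs/2^(j+1)..fs/2^j, so
  # kept levels 4..8 pass ~0.29-9.4 Hz; 3 Hz sits in level 5, 20 Hz in the
  # discarded level 2
  t <- seq(0, by = 1 / 150, length.out = 151)
  s3 <- sin(2 * pi * 3 * t)
  s20 <- sin(2 * pi * 20 * t)
  expect_gte(sum(wavelet_filter(s3)^2) / sum(s3^2), 0.8)
  expect_lte(sum(wavelet_filter(s20)^2) / sum(s20^2), 0.2)
})

test_that("wavelet filter is linear and respects shapes", {
  set.seed(2)
  a <- rnorm(151); b <- rnorm(151)
  lhs <- wavelet_filter(2 * a - 3 * b)
  rhs <- 2 * wavelet_filter(a) - 3 * wavelet_filter(b)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
  expect_equal(wavelet_filter(numeric(151)), numeric(151))
  # matrix input path is identical to per-column filtering
  m <- cbind(a, b)
  expect_equal(unname(wavelet_filter(m)),
               unname(cbind(wavelet_filter(a), wavelet_filter(b))))
  expect_error(wavelet_filter(rnorm(8)), "too short")
})

test_that("reject_epochs keeps at-threshold trials and is idempotent", {
  tr <- array(0, c(4L, 2L, 10L))
  tr[2, 1, 5] <- 101          # above threshold -> rejected
  tr[3, 2, 7] <- 100          # exactly at threshold -> kept (inclusive)
  tr[4, 1, 2] <- -150
  res <- reject_epochs(tr, 100)
  expect_equal(res$kept, c(1L, 3L))
  expect_equal(res$rejected_fraction, 0.5)
  # idempotent and order-preserving on the kept subset
  res2 <- reject_epochs(tr[res$kept, , , drop = FALSE], 100)
  expect_equal(res2$kept, seq_along(res$kept))
  expect_equal(res2$rejected_fraction, 0)
  expect_error(reject_epochs(tr + 1000, 100), "all epochs rejected")
})

test_that("baseline correction zeroes the baseline mean", {
  times <- default_times()
  # constant trace -> all zeros; step trace -> baseline 0, post-stim delta
  v <- ifelse(times < 0, 2, 7)
  ds <- baseline_correct(trace_dataset(v))
  expect_equal(unname(ds$data[1, 1, 1, times < 0]),
               rep(0, sum(times < 0)))
  expect_equal(unname(ds$data[1, 1, 1, times >= 0]),
               rep(5, sum(times >= 0)))
  set.seed(3)
  dr <- baseline_correct(trace_dataset(rnorm(151)))
  expect_lt(abs(mean(dr$data[1, 1, 1, times >= -200 & times < 0])), 1e-12)
  expect_error(baseline_correct(trace_dataset(v), c(500, 400)),
               "empty baseline")
})

test_that("trial averaging and Fourier resampling behave", {
  set.seed(4)
  one <- matrix(rnorm(3 * 20), 3)
  tr <- array(rep(one, each = 5), c(5, 3, 20))  # identical trials
  expect_equal(average_trials(tr), one)
  # 500 -> 128 Hz on a 1200 ms epoch
  n <- 600
  times <- (0:(n - 1)) * 1000 / 500
  ds <- erp_dataset(array(rnorm(n), c(1, 1, 1, n)), times, 500, "Cz")
  out <- resample_erp(ds, 128)
  expect_equal(dim(out$data)[4], round(n * 128 / 500))
  expect_equal(out$srate, 128)
  # DC is preserved exactly
  dc <- resample_erp(erp_dataset(array(3.5, c(1, 1, 1, n)), times, 500, "Cz"),
                     128)
  expect_equal(unname(dc$data[1, 1, 1, ]), rep(3.5, round(n * 128 / 500)))
})
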