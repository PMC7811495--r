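# Canny detector, region delineation, rectangle comparator

test_that("gradient magnitude and direction match the finite-difference oracle", {
  set.seed(11)
  img <- matrix(rnorm(256), 16)
  gr <- image_gradient(img)
  for (i in 2:15) for (j in 2:15) {
    gx <- (img[i, j + 1] - img[i, j - 1]) / 2
    gy <- (img[i + 1, j] - img[i - 1, j]) / 2
    expect_lt(abs(gr$magnitude[i, j] - sqrt(gx^2 + gy^2)), 1e-9)
    expect_lt(abs(gr$direction[i, j] - atan2(gy, gx)), 1e-9)
  }
  # Pythagorean check of the magnitude formula
  expect_equal(sqrt(3^2 + 4^2), 5)
  g <- image_gradient(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(max(g$magnitude), 0)
})

test_that("constant images give no edges; step images give one edge line", {
  expect_equal(sum(canny_edges(matrix(7, 20, 20))), 0L)
  step <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  e <- canny_edges(step, canny_params(gaussian_sigma = 0, t1 = 0.3, t2 = 0.1))
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_equal(cols, 10L)
  # invariance to adding a constant
  e2 <- canny_edges(step + 42,
                    canny_params(gaussian_sigma = 0, t1 = 0.3, t2 = 0.1))
  expect_identical(e, e2)
  # threshold scaling equivariance: scaling image and thresholds together
  e3 <- canny_edges(step * 10,
                    canny_params(gaussian_sigma = 0, t1 = 3, t2 = 1))
  expect_identical(e, e3)
  expect_error(canny_edges(matrix(0, 4, 4)), "too small")
  expect_error(canny_params(t1 = 1, t2 = 2), "t2 < t1")
})

test_that("an isolated blob is delineated and the masked mean is exact", {
  img <- blob_image(list(list(f0 = 5, fsd = 1.5, t0 = 300, tsd = 80,
                              amp = 1)))
  reg <- extract_region(img, c(3, 8))
  expect_true(reg$mask[which.min(abs(img$freqs - 5)),
                       which.min(abs(img$times - 300))])
  # brute-force masked-mean oracle, elementwise
  vals <- c()
  for (j in seq_len(ncol(img$values))) for (i in seq_len(nrow(img$values))) {
    if (reg$mask[i, j]) vals <- c(vals, img$values[i, j])
  }
  expect_identical(reg$grand_mean, mean(vals))
  # Eq.(3) degenerate case: the full-image mask gives the grand mean
  full <- region_from_mask(matrix(TRUE, 30, 151), img)
  expect_equal(full$grand_mean, mean(img$values))
})

test_that("with two blobs the band of interest selects the right component", {
  img <- blob_image(list(list(f0 = 4.5, fsd = 1.5, t0 = 250, tsd = 60,
                              amp = 1.2),
                         list(f0 = 12, fsd = 2.5, t0 = 550, tsd = 60,
                              amp = 1)))
  lo <- extract_region(img, c(3, 8))
  hi <- extract_region(img, c(10, 14))
  pk_lo <- which(lo$mask, arr.ind = TRUE)
  pk_hi <- which(hi$mask, arr.ind = TRUE)
  expect_lt(max(img$freqs[pk_lo[, 1]]), 10)
  expect_gt(max(img$freqs[pk_hi[, 1]]), 10)
  expect_equal(count_ero_regions(img, list(c(3, 8), c(10, 14))), 2L)
  # a band whose maximum falls outside any closed component
  flat <- blob_image(list(list(f0 = 4.5, fsd = 1.5, t0 = 300, tsd = 60,
                               amp = 1)))
  expect_error(extract_region(flat, c(12, 15)), class = "no_region_found")
})

test_that("per-subject region means equal brute-force masked means", {
  set.seed(12)
  obj <- small_sim(n = 4L, snr = 10, seed = 2L)
  tf <- morlet_tfr(obj$sim$data, channels = c("Cz", "FCz"))
  img <- tfr_image(tf, c("Cz", "FCz"), 1L)
  mask <- matrix(FALSE, 30, 151)
  mask[8:14, 60:95] <- TRUE
  reg <- region_from_mask(mask, img, tfrs = tf)
  for (s in 1:4) {
    m <- apply(tf$power[s, 1, , , ], c(2, 3), mean)
    expect_identical(unname(reg$means[s, 1]), mean(m[mask]))
  }
})

test_that("rectangle regions honour their windows and degenerate cases", {
  img <- blob_image(list(list(f0 = 5, fsd = 1.5, t0 = 250, tsd = 70,
                              amp = 1)))
  r <- rectangle_region(img, c(100, 300), c(3, 7))
  mi <- which(r$mask, arr.ind = TRUE)
  expect_true(all(img$freqs[mi[, 1]] >= 3 & img$freqs[mi[, 1]] <= 7))
  expect_true(all(img$times[mi[, 2]] >= 100 & img$times[mi[, 2]] <= 300))
  # full-extent rectangle equals the grand mean
  full <- rectangle_region(img, c(-200, 800), c(0.5, 15.5))
  expect_equal(full$grand_mean, mean(img$values))
  # constant image: any rectangle mean equals the constant
  cimg <- img; cimg$values[] <- 2.5
  expect_equal(rectangle_region(cimg, c(0, 400), c(2, 9))$grand_mean, 2.5)
  expect_error(rectangle_region(img, c(900, 950), c(3, 7)), "empty rectangle")
  # monotonicity: growing the rectangle moves the mean toward the grand mean
  g <- mean(img$values)
  small <- rectangle_region(img, c(150, 350), c(3.5, 7))$grand_mean
  mid <- rectangle_region(img, c(0, 500), c(2, 10))$grand_mean
  expect_gt(abs(small - g), abs(mid - g))
})
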