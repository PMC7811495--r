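# ---- filter construction -----------------------------------------------------
#
# Biorthogonal spline-family lowpass pairs are built from the classical
# two-channel half-band identity.  Writing y = sin^2(w/2), the product of the
# two lowpass responses must equal 2 * cos(w/2)^(2L) * P(y) with
#   P(y) = sum_{k=0}^{L-1} choose(L-1+k, k) y^k,
# the Daubechies half-band polynomial.  A (Nr, Nd) pair with Nr + Nd = 2L
# splits the cos powers as Nr and Nd and factorises P(y) between the two
# filters.  The named 6.8 pair allocates one complex-conjugate root pair of
# P to the 6-vanishing-moment filter (11 taps) and the remaining quartic to
# the 8-moment filter (17 taps); this reproduces the canonical taps shipped
# by the usual wavelet toolboxes.

# polynomial helpers: coefficient vectors, lowest degree first
.poly_mul <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

.poly_pow <- function(a, k) {
  out <- 1
  for (i in seq_len(k)) out <- .poly_mul(out, a)
  out
}

# Laurent series on integer grid: list(v = taps, t0 = index of first tap)
.laur <- function(v, t0) list(v = as.numeric(v), t0 = as.integer(t0))

.laur_mul <- function(a, b) .laur(.poly_mul(a$v, b$v), a$t0 + b$t0)

# Daubechies half-band polynomial P(y), degree L-1
.daub_halfband <- function(L) choose(L - 1 + 0:(L - 1), 0:(L - 1))

# express a polynomial Q(y) with y = sin^2(w/2) = (2 - z - 1/z)/4 as a
# symmetric Laurent series in z
.q_to_laurent <- function(q) {
  y <- .laur(c(-0.25, 0.5, -0.25), -1L)
  acc <- .laur(q[1], 0L)
  yp <- .laur(1, 0L)
  for (k in seq_len(length(q) - 1L)) {
    yp <- .laur_mul(yp, y)
    term <- yp
    term$v <- term$v * q[k + 1L]
    lo <- min(acc$t0, term$t0)
    hi <- max(acc$t0 + length(acc$v), term$t0 + length(term$v)) - 1L
    v <- numeric(hi - lo + 1L)
    v[(acc$t0 - lo + 1L):(acc$t0 - lo + length(acc$v))] <- acc$v
    idx <- (term$t0 - lo + 1L):(term$t0 - lo + length(term$v))
    v[idx] <- v[idx] + term$v
    acc <- .laur(v, lo)
  }
  acc
}

# cos(w/2)^N as Laurent series (N even: integer grid, symmetric)
.cos_pow_laurent <- function(N) {
  stopifnot(N %% 2L == 0L)
  .laur(choose(N, 0:N) / 2^N, -N %/% 2L)
}

# real factorisation of P(y): a degree-2 factor (one conjugate root pair)
# and the complementary factor.  The conjugate pair whose real part is
# smallest in magnitude pairs with the 6-moment filter; this reproduces the
# canonical 11/17-tap 6.8 taps.  Both factors are normalised to 1 at y = 0
# so their product is exactly P.
.split_halfband <- function(L) {
  p <- .daub_halfband(L)
  r <- polyroot(p)
  cc <- r[Im(r) > 1e-9]
  pick <- cc[which.min(abs(Re(cc)))]
  q_short <- c(Mod(pick)^2, -2 * Re(pick), 1)           # (y - p)(y - conj(p))
  q_short <- q_short / q_short[1L]
  rest <- r[abs(r - pick) > 1e-9 & abs(r - Conj(pick)) > 1e-9]
  q_long <- 1 + 0i
  for (rt in rest) q_long <- .poly_mul(q_long, c(-rt, 1))
  q_long <- Re(q_long) / Re(q_long[1L])
  list(short = q_short, long = q_long)
}

#' Construct a biorthogonal wavelet filter bank
#'
#' Builds the analysis/synthesis lowpass and highpass filters for the
#' biorthogonal families used by the band filter.  `"bior6.8"` uses the
#' 17-tap filter on the analysis side; `"rbio6.8"` (the default mother
#' wavelet of [wavelet_filter()]) swaps analysis and synthesis so the 11-tap
#' filter analyses.  Filters are returned on an integer grid as
#' `list(v, t0)` with `t0` the index of the first tap; all four satisfy the
#' exact perfect-reconstruction identity.
#'
#' @param name wavelet name, one of `"bior6.8"`, `"rbio6.8"`.
#' @return list with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`, `name`.
#' @export
wavelet_filters <- function(name = "rbio6.8") {
  if (!name %in% c("bior6.8", "rbio6.8")) {
    stop("unknown mother wavelet: ", name)
  }
  L <- 7L                                   # (6 + 8) / 2
  qs <- .split_halfband(L)
  # 6-moment side: cos^6 * quadratic factor -> 11 taps
  h6 <- .laur_mul(.cos_pow_laurent(6L), .q_to_laurent(qs$short))
  # 8-moment side: cos^8 * quartic factor -> 17 taps
  h8 <- .laur_mul(.cos_pow_laurent(8L), .q_to_laurent(qs$long))
  h6$v <- h6$v * sqrt(2)
  h8$v <- h8$v * sqrt(2)
  if (name == "bior6.8") {
    hd <- h8; hr <- h6
  } else {
    hd <- h6; hr <- h8
  }
  # alias-cancelling highpass pair: Gd(z) = z^-1 Hr(-z), Gr(z) = z Hd(-z)
  gd <- .laur(hr$v * (-1)^(hr$t0:(hr$t0 + length(hr$v) - 1L)), hr$t0 + 1L)
  gr <- .laur(hd$v * (-1)^(hd$t0:(hd$t0 + length(hd$v) - 1L)), hd$t0 - 1L)
  list(dec_lo = hd, dec_hi = gd, rec_lo = hr, rec_hi = gr, name = name)
}

# ---- convolution machinery ---------------------------------------------------

# full linear convolution of every column of x with taps v (FFT based)
.conv_cols <- function(x, v) {
  n <- nrow(x); m <- length(v)
  nf <- n + m - 1L
  X <- stats::mvfft(rbind(x, matrix(0, nf - n, ncol(x))))
  H <- stats::fft(c(v, numeric(nf - m)))
  Re(stats::mvfft(X * H, inverse = TRUE)) / nf
}

# signals carry an integer start index t0 so the dyadic phase is unambiguous
.dn2 <- function(x, t0) {
  idx <- which((t0 + seq_len(nrow(x)) - 1L) %% 2L == 0L)
  list(x = x[idx, , drop = FALSE], t0 = t0 + idx[1L] - 1L)
}

.up2 <- function(x, t0) {
  out <- matrix(0, 2L * nrow(x), ncol(x))
  out[seq(1L, 2L * nrow(x), by = 2L), ] <- x
  list(x = out, t0 = t0)
}

.analysis_step <- function(x, t0, fb) {
  lo <- .conv_cols(x, fb$dec_lo$v); hi <- c1 <- NULL
  a <- .dn2(lo, t0 + fb$dec_lo$t0)
  hi <- .conv_cols(x, fb$dec_hi$v)
  d <- .dn2(hi, t0 + fb$dec_hi$t0)
  a$t0 <- a$t0 %/% 2L          # coefficients live on the coarser grid
  d$t0 <- d$t0 %/% 2L
  list(a = a, d = d)
}

.synthesis_step <- function(a, d, fb, out_t0, out_len) {
  ua <- .up2(a$x, 2L * a$t0)
  ud <- .up2(d$x, 2L * d$t0)
  ra <- .conv_cols(ua$x, fb$rec_lo$v); ta <- ua$t0 + fb$rec_lo$t0
  rd <- .conv_cols(ud$x, fb$rec_hi$v); td <- ud$t0 + fb$rec_hi$t0
  lo <- min(ta, td)
  hi <- max(ta + nrow(ra), td + nrow(rd)) - 1L
  acc <- matrix(0, hi - lo + 1L, ncol(ra))
  acc[(ta - lo + 1L):(ta - lo + nrow(ra)), ] <- ra
  idx <- (td - lo + 1L):(td - lo + nrow(rd))
  acc[idx, ] <- acc[idx, ] + rd
  # crop to the requested support
  keep <- (out_t0 - lo + 1L):(out_t0 - lo + out_len)
  stopifnot(keep[1L] >= 1L, keep[length(keep)] <= nrow(acc))
  acc[keep, , drop = FALSE]
}

# multilevel analysis of column signals; returns per-level detail and final
# approximation with their supports, so synthesis can crop exactly
.wt_analyze <- function(x, fb, n_levels) {
  details <- vector("list", n_levels)
  supports <- vector("list", n_levels)
  cur <- x; t0 <- 0L
  for (j in seq_len(n_levels)) {
    supports[[j]] <- list(t0 = t0, len = nrow(cur))
    st <- .analysis_step(cur, t0, fb)
    details[[j]] <- st$d
    cur <- st$a$x; t0 <- st$a$t0
  }
  list(details = details, approx = list(x = cur, t0 = t0),
       supports = supports, n = nrow(x))
}

.wt_synthesize <- function(dec, fb, keep_details, keep_approx) {
  n_levels <- length(dec$details)
  a <- dec$approx
  if (!keep_approx) a$x[] <- 0
  for (j in rev(seq_len(n_levels))) {
    d <- dec$details[[j]]
    if (!(j %in% keep_details)) d$x[] <- 0
    sup <- dec$supports[[j]]
    x <- .synthesis_step(a, d, fb, sup$t0, sup$len)
    a <- list(x = x, t0 = sup$t0)
  }
  a$x
}

#' Multilevel discrete wavelet band filter
#'
#' Decomposes each signal to `n_levels` with the chosen biorthogonal mother
#' wavelet and reconstructs from a subset of detail levels (the
#' approximation and the discarded details are zeroed).  With `fs = 150` Hz
#' and the default kept levels 4--8 the filter passes roughly 0.3--9.4 Hz,
#' i.e. the delta and theta range carrying the N2/P3 oscillations.  Signals
#' are extended symmetrically at the epoch edges before analysis
#' (configurable via `boundary`); reconstruction crops back to the input
#' support, and keeping every level plus the approximation reproduces the
#' input to floating-point accuracy.
#'
#' @param x numeric vector, a time-by-signals matrix, or an [erp_dataset].
#' @param spec a [wavelet_filter_spec()].
#' @return object of the same shape/class as `x`.
#' @export
wavelet_filter <- function(x, spec = wavelet_filter_spec()) {
  if (inherits(x, "erp_dataset")) {
    dm <- dim(x$data)
    flat <- matrix(aperm(x$data, c(4L, 1L, 2L, 3L)), nrow = dm[4L])
    out <- wavelet_filter(flat, spec)
    x$data <- aperm(array(out, c(dm[4L], dm[1L], dm[2L], dm[3L])),
                    c(2L, 3L, 4L, 1L))
    return(x)
  }
  vec_in <- is.null(dim(x))
  xm <- if (vec_in) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  fb <- wavelet_filters(spec$mother)
  flen <- length(fb$dec_lo$v)
  if (nrow(xm) < flen) stop("signal too short for wavelet decomposition")
  n <- nrow(xm)
  pad <- 0L
  if (identical(spec$boundary, "symmetric")) {
    pad <- min(n - 1L, 4L * flen)
    xm <- rbind(xm[(pad + 1L):2L, , drop = FALSE], xm,
                xm[(n - 1L):(n - pad), , drop = FALSE])
  }
  dec <- .wt_analyze(xm, fb, spec$n_levels)
  rec <- .wt_synthesize(dec, fb, spec$keep_detail_levels, spec$keep_approx)
  rec <- rec[(pad + 1L):(pad + n), , drop = FALSE]
  if (vec_in) drop(rec) else rec
}

#' Wavelet band-filter specification
#'
#' @param mother mother wavelet name (default `"rbio6.8"`).
#' @param n_levels decomposition depth (default 8).
#' @param keep_detail_levels detail levels retained for reconstruction
#'   (default `4:8`); must lie in `1:n_levels`.
#' @param keep_approx retain the level-`n_levels` approximation (default
#'   `FALSE`: the approximation is zeroed, making the filter band-pass).
#' @param boundary `"symmetric"` (default) or `"zero"` signal extension.
#' @return list with class `"wavelet_filter_spec"`.
#' @export
wavelet_filter_spec <- function(mother = "rbio6.8", n_levels = 8L,
                                keep_detail_levels = 4:8,
                                keep_approx = FALSE,
                                boundary = c("symmetric", "zero")) {
  boundary <- match.arg(boundary)
  n_levels <- as.integer(n_levels)
  keep_detail_levels <- as.integer(keep_detail_levels)
  if (length(keep_detail_levels) &&
      (min(keep_detail_levels) < 1L || max(keep_detail_levels) > n_levels)) {
    stop("keep_detail_levels must lie in 1..n_levels")
  }
  structure(list(mother = mother, n_levels = n_levels,
                 keep_detail_levels = keep_detail_levels,
                 keep_approx = keep_approx, boundary = boundary),
            class = "wavelet_filter_spec")
}
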