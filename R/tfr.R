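#' Complex Morlet time-frequency specification
#'
#' The mother wavelet is `psi(t) = (pi*fb)^(-1/2) exp(2i*pi*fc*t) exp(-t^2/fb)`
#' with bandwidth `fb` (s^2) and centre frequency `fc` (Hz); the daughter
#' analysing frequency `f` is the L2-normalised `s^(-1/2) psi(t/s)` with
#' scale `s = fc/f`.  With the default `fb = fc = 1` the low-frequency
#' daughters span roughly one cycle, trading frequency resolution for time
#' resolution; this deliberately coarse setting is kept as-is.
#'
#' @param fb bandwidth parameter, s^2 (default 1).
#' @param fc centre frequency, Hz (default 1).
#' @param freqs explicit frequency vector (Hz), or `NULL` to build one.
#' @param fmin,fmax,n_bins frequency-grid limits and size used when
#'   `freqs` is `NULL` (defaults 1--15 Hz, 30 bins).
#' @param spacing `"log"` (default) or `"linear"` bin spacing.
#' @param baseline_window ms pair for baseline power subtraction.
#' @param padding `"zero"` (default) or `"symmetric"` signal extension for
#'   the FFT convolution.  Mirrored extension duplicates both signal and
#'   noise beyond the epoch edge, which doubles the low-frequency edge
#'   amplitude (4x the power) and can dominate the delta band; zero
#'   extension lets edge power decay instead.  Interior values (outside
#'   the cone of influence) are independent of this choice.
#' @return list of class `morlet_spec`.
#' @export
morlet_spec <- function(fb = 1, fc = 1, freqs = NULL, fmin = 1, fmax = 15,
                        n_bins = 30L, spacing = c("log", "linear"),
                        baseline_window = c(-200, 0),
                        padding = c("zero", "symmetric")) {
  spacing <- match.arg(spacing)
  padding <- match.arg(padding)
  if (is.null(freqs)) {
    freqs <- if (spacing == "log") exp(seq(log(fmin), log(fmax),
                                           length.out = n_bins))
             else seq(fmin, fmax, length.out = n_bins)
  }
  stopifnot(all(diff(freqs) > 0), all(freqs > 0))
  structure(list(fb = fb, fc = fc, freqs = freqs,
                 baseline_window = baseline_window, padding = padding),
            class = "morlet_spec")
}

# complex Morlet daughter sampled at dt for analysed frequency f
.morlet_daughter <- function(f, fb, fc, dt) {
  s <- fc / f
  half <- ceiling(5 * s * sqrt(fb / 2) / dt)
  t <- (-half:half) * dt
  (1 / sqrt(s)) * (pi * fb)^(-0.5) *
    exp(2i * pi * fc * t / s - t^2 / (fb * s^2))
}

# CWT power of column signals: returns freqs x time x traces array
.morlet_power <- function(x, dt, spec) {
  vec_in <- is.null(dim(x))
  xm <- if (vec_in) matrix(x, ncol = 1L) else x
  n <- nrow(xm)
  kernels <- lapply(spec$freqs, .morlet_daughter, fb = spec$fb, fc = spec$fc,
                    dt = dt)
  maxh <- max(vapply(kernels, function(k) (length(k) - 1L) %/% 2L, 1L))
  if (identical(spec$padding, "symmetric")) {
    pad <- min(n - 1L, maxh)
    xe <- rbind(xm[(pad + 1L):2L, , drop = FALSE], xm,
                xm[(n - 1L):(n - pad), , drop = FALSE])
  } else {
    pad <- 0L
    xe <- xm
  }
  ne <- nrow(xe)
  L <- ne + 2L * maxh
  XF <- stats::mvfft(rbind(xe, matrix(0, L - ne, ncol(xm))))
  out <- array(0, c(length(spec$freqs), n, ncol(xm)))
  for (i in seq_along(kernels)) {
    k <- Conj(kernels[[i]]) * dt
    h <- (length(kernels[[i]]) - 1L) %/% 2L
    KF <- stats::fft(c(k, complex(real = numeric(L - length(k)))))
    conv <- stats::mvfft(XF * KF, inverse = TRUE) / L
    rows <- (h + pad + 1L):(h + pad + n)
    out[i, , ] <- Mod(conv[rows, , drop = FALSE])^2
  }
  if (vec_in) out[, , 1L] else out
}

#' Morlet time-frequency representation of an ERP dataset
#'
#' Convolves every subject/condition/channel trace with the complex Morlet
#' daughters and returns squared-magnitude power (uV^2/Hz), optionally
#' baseline-corrected by subtracting, per frequency, the mean power over
#' the baseline window.  Convolution is FFT-based with symmetric signal
#' extension at the epoch edges; the cone of influence is not masked.
#'
#' @param data an [erp_dataset].
#' @param spec a [morlet_spec()].
#' @param channels channel labels to transform (default: all).
#' @param baseline subtract baseline mean power (default `TRUE`).
#' @return object of class `tfr_set`: `power`
#'   `[subjects, conditions, channels, freqs, time]`, `freqs`, `times`,
#'   labels and a `baseline_corrected` flag.
#' @export
morlet_tfr <- function(data, spec = morlet_spec(), channels = NULL,
                       baseline = TRUE) {
  stopifnot(inherits(data, "erp_dataset"))
  if (max(spec$freqs) > data$srate / 2) {
    stop("frequencies above Nyquist (", data$srate / 2, " Hz)")
  }
  ch_idx <- if (is.null(channels)) seq_along(data$channel_labels)
            else match(channels, data$channel_labels)
  if (anyNA(ch_idx)) stop("unknown channel requested")
  d <- dim(data$data)
  n_s <- d[1L]; n_c <- d[2L]; n_ch <- length(ch_idx); n_t <- d[4L]
  sub <- data$data[, , ch_idx, , drop = FALSE]
  flat <- matrix(aperm(sub, c(4L, 1L, 2L, 3L)), nrow = n_t)
  pw <- .morlet_power(flat, 1 / data$srate, spec)        # f x t x traces
  n_f <- length(spec$freqs)
  power <- aperm(array(pw, c(n_f, n_t, n_s, n_c, n_ch)), c(3L, 4L, 5L, 1L, 2L))
  out <- structure(list(power = power, freqs = spec$freqs, times = data$times,
                        channel_labels = data$channel_labels[ch_idx],
                        condition_labels = data$condition_labels,
                        subject_ids = data$subject_ids,
                        baseline_window = spec$baseline_window,
                        baseline_corrected = FALSE, spec = spec),
                   class = "tfr_set")
  if (baseline) out <- baseline_correct_tfr(out) else out
}

#' Subtract baseline mean power from a TFR set
#'
#' Per subject/condition/channel/frequency, subtracts the mean power over
#' the baseline window (right-open) from every time point.
#'
#' @param tfrs a `tfr_set`.
#' @param window ms pair; defaults to the window in the set's spec.
#' @return the corrected `tfr_set` with `baseline_corrected = TRUE`.
#' @export
baseline_correct_tfr <- function(tfrs, window = NULL) {
  stopifnot(inherits(tfrs, "tfr_set"))
  if (is.null(window)) window <- tfrs$baseline_window
  sel <- tfrs$times >= window[1L] & tfrs$times < window[2L]
  if (!any(sel)) stop("empty baseline window")
  bl <- apply(tfrs$power[, , , , sel, drop = FALSE], 1:4, mean)
  tfrs$power <- tfrs$power - as.vector(bl)
  tfrs$baseline_corrected <- TRUE
  tfrs
}

#' @export
print.tfr_set <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_set> %d subj x %d cond x %d chan, %d freqs (%.2f-%.2f Hz) x %d samples%s\n",
    d[1L], d[2L], d[3L], d[4L], min(x$freqs), max(x$freqs), d[5L],
    if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' Grand-average TFR image over electrodes and subjects
#'
#' @param tfrs a `tfr_set`.
#' @param electrodes channel labels averaged over.
#' @param condition condition index or label (default first).
#' @return object of class `tfr_image`: `values` (freqs x time), `freqs`,
#'   `times`, `electrodes`.
#' @export
tfr_image <- function(tfrs, electrodes = NULL, condition = 1L) {
  stopifnot(inherits(tfrs, "tfr_set"))
  if (is.character(condition)) {
    condition <- match(condition, tfrs$condition_labels)
  }
  ch <- if (is.null(electrodes)) seq_along(tfrs$channel_labels)
        else match(electrodes, tfrs$channel_labels)
  if (anyNA(ch)) stop("unknown electrode")
  vals <- apply(tfrs$power[, condition, ch, , , drop = FALSE], c(4L, 5L), mean)
  structure(list(values = vals, freqs = tfrs$freqs, times = tfrs$times,
                 electrodes = tfrs$channel_labels[ch]),
            class = "tfr_image")
}

#' Flatten a TFR set into the cases-by-(freq x time) matrix
#'
#' Rows are channel-major within condition within subject (cases =
#' channels x conditions x subjects); columns are frequency-major
#' (all frequencies of the first retained time point, then the next).
#' The time axis is restricted to `time_window` (right-open).
#'
#' @param tfrs a `tfr_set`.
#' @param time_window ms pair or `NULL` for the full epoch.
#' @return list with `X` (cases x variables), `row_index`, `freqs`,
#'   `times`, and the axis labels.
#' @export
build_tfr_matrix <- function(tfrs, time_window = NULL) {
  stopifnot(inherits(tfrs, "tfr_set"))
  sel <- if (is.null(time_window)) seq_along(tfrs$times)
         else which(tfrs$times >= time_window[1L] & tfrs$times < time_window[2L])
  d <- dim(tfrs$power)
  n_s <- d[1L]; n_c <- d[2L]; n_ch <- d[3L]; n_f <- d[4L]
  ri <- expand.grid(channel = seq_len(n_ch), condition = seq_len(n_c),
                    subject = seq_len(n_s))[, 3:1]
  X <- matrix(0, n_s * n_c * n_ch, n_f * length(sel))
  row <- 1L
  for (s in seq_len(n_s)) for (co in seq_len(n_c)) for (ch in seq_len(n_ch)) {
    X[row, ] <- as.vector(tfrs$power[s, co, ch, , sel])   # frequency-major
    row <- row + 1L
  }
  list(X = X, row_index = ri, freqs = tfrs$freqs, times = tfrs$times[sel],
       time_sel = sel,
       dims = c(subjects = n_s, conditions = n_c, channels = n_ch))
}

#' TFA-PCA comparator: PCA + Varimax on flattened TFRs with weighting
#'
#' Performs covariance-matrix PCA (Kaiser-normalised Varimax rotation) on
#' the cases-by-(freq x time) matrix of baseline-corrected TFRs, retains
#' components up to `variance_threshold` cumulative explained variance,
#' and for each selected component forms the weighted TFR: the component's
#' loading surface (reshaped to freq x time) multiplied elementwise into
#' every case's original TFR.
#'
#' @param tfrs a baseline-corrected `tfr_set`.
#' @param variance_threshold cumulative explained-variance fraction
#'   (default 0.99).
#' @param select component indices to weight (default: all retained).
#' @param time_window ms pair restricting the analysed samples.
#' @return list of class `tfa_pca` with `loadings` (variables x R),
#'   `explained_variance_pct`, `R`, `weighted` (named list of 5-D arrays
#'   shaped like `tfrs$power` over the analysed window), `freqs`, `times`.
#' @export
tfa_pca <- function(tfrs, variance_threshold = 0.99, select = NULL,
                    time_window = NULL) {
  stopifnot(inherits(tfrs, "tfr_set"))
  if (!tfrs$baseline_corrected) stop("TFRs must be baseline-corrected")
  tm <- build_tfr_matrix(tfrs, time_window)
  X <- tm$X
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  n <- nrow(Xc)
  if (ncol(Xc) <= n) {
    ev <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    lambda <- pmax(ev$values, 0)
    V <- ev$vectors
  } else {
    ev <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
    lambda <- pmax(ev$values, 0)
    V <- crossprod(Xc, ev$vectors)
    V <- sweep(V, 2L, pmax(sqrt(colSums(V^2)), 1e-300), "/")
  }
  expl <- 100 * lambda / sum(lambda)
  R <- retained_count(lambda, variance_threshold)
  L <- V[, seq_len(R), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(R)]), R)
  if (R > 1L) {
    vm <- stats::varimax(L, normalize = TRUE)   # Kaiser normalization
    L <- L %*% vm$rotmat
  }
  if (is.null(select)) select <- seq_len(R)
  stopifnot(all(select >= 1L & select <= R))
  d <- dim(tfrs$power)
  n_f <- d[4L]; n_t <- length(tm$time_sel)
  # weighted TFR: loading surface multiplied elementwise into each case
  weighted <- lapply(select, function(r) {
    surf <- matrix(L[, r], n_f, n_t)
    base <- tfrs$power[, , , , tm$time_sel, drop = FALSE]
    arr <- array(0, dim(base))
    for (fi in seq_len(n_f)) {
      arr[, , , fi, ] <- base[, , , fi, ] *
        rep(surf[fi, ], each = d[1L] * d[2L] * d[3L])
    }
    arr
  })
  names(weighted) <- paste0("C", select)
  structure(list(loadings = L, explained_variance_pct = expl, R = R,
                 selected = select, weighted = weighted, freqs = tfrs$freqs,
                 times = tm$times, row_index = tm$row_index,
                 matrix_dim = dim(X)),
            class = "tfa_pca")
}
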