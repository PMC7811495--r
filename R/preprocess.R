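#' Reject epochs exceeding an absolute voltage threshold
#'
#' A trial is kept iff the maximum of `|value|` over channels and samples
#' is at most `threshold_uv` (the comparison is inclusive: a trial peaking
#' exactly at the threshold is kept).
#'
#' @param trials numeric array `[trials, channels, time]`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @param label context string used in the all-rejected error message.
#' @return list with sorted `kept` indices and `rejected_fraction`.
#' @export
reject_epochs <- function(trials, threshold_uv = 100, label = "dataset") {
  stopifnot(threshold_uv > 0, length(dim(trials)) == 3L)
  peak <- apply(abs(trials), 1L, max)
  kept <- which(peak <= threshold_uv)
  if (length(kept) == 0L) {
    stop("all epochs rejected for ", label)
  }
  list(kept = kept,
       rejected_fraction = 1 - length(kept) / dim(trials)[1L])
}

#' Baseline-correct an ERP dataset
#'
#' Subtracts, per subject/condition/channel, the mean voltage over the
#' baseline window (right-open: samples with `window[1] <= t < window[2]`).
#'
#' @param data an [erp_dataset].
#' @param window baseline window in ms (default `c(-200, 0)`).
#' @return the corrected [erp_dataset].
#' @export
baseline_correct <- function(data, window = c(-200, 0)) {
  stopifnot(inherits(data, "erp_dataset"))
  sel <- data$times >= window[1L] & data$times < window[2L]
  if (!any(sel)) stop("empty baseline window")
  bl <- apply(data$data[, , , sel, drop = FALSE], 1:3, mean)
  data$data <- data$data - as.vector(bl)   # recycles over the time dimension
  data
}

#' Average single trials into an ERP
#'
#' @param trials numeric array `[trials, channels, time]`.
#' @return `channels x time` matrix (the arithmetic mean across trials).
#' @export
average_trials <- function(trials) {
  stopifnot(length(dim(trials)) == 3L, dim(trials)[1L] >= 1L)
  apply(trials, c(2L, 3L), mean)
}

# Fourier (FFT) resampling of the columns-of-time matrix, scipy style:
# truncate/zero-pad the spectrum, preserving DC and scaling by m/n.
.fft_resample <- function(x, m) {
  vec_in <- is.null(dim(x))
  xm <- if (vec_in) matrix(x, ncol = 1L) else x
  n <- nrow(xm)
  X <- stats::mvfft(xm)
  Y <- matrix(0 + 0i, m, ncol(xm))
  nh <- min(n, m)
  half <- nh %/% 2L
  Y[1:(half + 1L), ] <- X[1:(half + 1L), , drop = FALSE]
  if (half > 0L) {
    Y[(m - half + 1L):m, ] <- X[(n - half + 1L):n, , drop = FALSE]
  }
  if (nh %% 2L == 0L && m > n) {                 # split the shared Nyquist bin
    Y[half + 1L, ] <- Y[half + 1L, ] / 2
    Y[m - half + 1L, ] <- Y[half + 1L, ]
  }
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  if (vec_in) drop(out) else out
}

#' Resample an ERP dataset to a new sampling rate
#'
#' Fourier-domain resampling with implicit anti-aliasing (the spectrum is
#' truncated at the new Nyquist frequency); output length is
#' `round(n * new_srate / srate)` and the time axis is rebuilt from the
#' epoch start at the new rate.
#'
#' @param data an [erp_dataset].
#' @param new_srate target sampling rate, Hz.
#' @return the resampled [erp_dataset].
#' @export
resample_erp <- function(data, new_srate) {
  stopifnot(inherits(data, "erp_dataset"), new_srate > 0)
  dm <- dim(data$data)
  n <- dm[4L]
  m <- round(n * new_srate / data$srate)
  flat <- matrix(aperm(data$data, c(4L, 1L, 2L, 3L)), nrow = n)
  out <- .fft_resample(flat, m)
  arr <- aperm(array(out, c(m, dm[1L], dm[2L], dm[3L])), c(2L, 3L, 4L, 1L))
  times <- data$times[1L] + (seq_len(m) - 1L) * 1000 / new_srate
  erp_dataset(arr, times, new_srate, data$channel_labels,
              data$condition_labels, data$subject_ids)
}
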