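#' Epoched/averaged ERP container
#'
#' Thin container for subject-by-condition-by-channel-by-time voltage data
#' (microvolts) with axis metadata.
#'
#' @param data 4-D numeric array `[subjects, conditions, channels, time]`.
#' @param times time axis in ms, uniformly spaced at `1000/srate`.
#' @param srate sampling rate in Hz.
#' @param channel_labels,condition_labels,subject_ids axis labels.
#' @return object of class `erp_dataset`.
#' @export
erp_dataset <- function(data, times, srate, channel_labels,
                        condition_labels = "cond1",
                        subject_ids = NULL) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 4L)
  if (anyNA(data) || any(!is.finite(data))) stop("non-finite values in data")
  if (length(times) != dim(data)[4L]) stop("times length != time dimension")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1000 / srate)) > 1e-6) {
    stop("times must be strictly increasing at 1000/srate ms spacing")
  }
  if (length(channel_labels) != dim(data)[3L]) stop("channel label mismatch")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(dim(data)[1L]))
  structure(list(data = data, times = as.numeric(times), srate = srate,
                 channel_labels = as.character(channel_labels),
                 condition_labels = as.character(condition_labels),
                 subject_ids = as.character(subject_ids)),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<erp_dataset> %d subjects x %d conditions x %d channels x %d samples\n",
    d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  %.1f..%.1f ms at %g Hz\n", x$times[1L],
              x$times[length(x$times)], x$srate))
  invisible(x)
}

# evaluate a Hann (raised-cosine) lobe, unit peak, zero outside its support
.hann_lobe <- function(t, peak, width) {
  u <- (t - peak) / width
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Default four-source model of the synthetic ERP world
#'
#' Defines the N1, P2, N2 and P3 generators: Hann-lobe temporal waveforms
#' (unit peak, silent during the pre-stimulus baseline) confined to their
#' peak windows, spatial-Gaussian topographies on the 65-channel montage
#' peaking at Fz, CPz, FCz and Cz respectively, and source amplitudes in
#' microvolts.  N2 (peaking in 260--400 ms at FCz) and P3 (370--580 ms at
#' Cz) carry per-subject latency and amplitude jitter; P3 is made several
#' times stronger than N2 so that in the linear mixture the N2 theta
#' response is masked by the P3 delta response (source time-frequency peak
#' powers near 0.3 and 3 uV^2/Hz at the peak electrodes).
#'
#' @param n_channels number of electrodes (default 65).
#' @param srate sampling rate, Hz (default 150).
#' @param epoch_window epoch limits in ms (default `c(-200, 800)`).
#' @param jittered_sources names of sources receiving per-subject jitter.
#' @param latency_jitter_sd latency jitter SD in ms (default 20).
#' @param amplitude_jitter_sd SD of the positive amplitude scale factor
#'   centred at 1 (default 0.1).
#' @param snr_db target SNR in dB, or `NA` for noise-free data.
#' @param seed integer seed driving all randomness of the generator.
#' @return object of class `source_model`.
#' @export
make_default_sources <- function(n_channels = 65L, srate = 150,
                                 epoch_window = c(-200, 800),
                                 jittered_sources = c("N2", "P3"),
                                 latency_jitter_sd = 20,
                                 amplitude_jitter_sd = 0.1,
                                 snr_db = NA_real_, seed = 1L) {
  montage <- default_montage()[seq_len(n_channels), , drop = FALSE]
  n_time <- round(diff(epoch_window) / 1000 * srate) + 1L
  times <- epoch_window[1L] + (seq_len(n_time) - 1L) * 1000 / srate
  spec <- list(
    N1 = list(peak = 110, width =  90, polarity = -1, channel = "Fz",
              amplitude = 2.5, window = c(65, 155)),
    P2 = list(peak = 200, width = 110, polarity = +1, channel = "CPz",
              amplitude = 3.0, window = c(145, 255)),
    N2 = list(peak = 330, width = 140, polarity = -1, channel = "FCz",
              amplitude = 1.6, window = c(260, 400)),
    P3 = list(peak = 475, width = 210, polarity = +1, channel = "Cz",
              amplitude = 5.5, window = c(370, 580))
  )
  sources <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    structure(list(
      name = nm,
      peak_ms = s$peak, width_ms = s$width,
      peak_window = s$window,
      polarity = s$polarity,
      amplitude_uv = s$amplitude,
      peak_channel = s$channel,
      waveform = s$polarity * s$amplitude * .hann_lobe(times, s$peak, s$width),
      topography = .gaussian_topography(montage, s$channel)
    ), class = "source_spec")
  })
  names(sources) <- names(spec)
  structure(list(
    n_channels = n_channels, srate = srate, epoch_window = epoch_window,
    times = times, montage = montage, sources = sources,
    jittered_sources = jittered_sources,
    latency_jitter_sd = latency_jitter_sd,
    amplitude_jitter_sd = amplitude_jitter_sd,
    snr_db = snr_db, seed = as.integer(seed)
  ), class = "source_model")
}

#' Simulate a multi-subject ERP dataset with known sources
#'
#' For every subject each jittered source is shifted in time by a Gaussian
#' latency draw and scaled by a positive Gaussian amplitude factor
#' (truncated at 0.1); the per-channel data are the sum over sources of
#' `scale * waveform(t - shift) (x) topography`, plus white Gaussian noise
#' calibrated so that `10 log10(P_signal / P_noise)` matches `snr_db`,
#' where `P_signal` is the subject's mean squared mixed signal over
#' channels and post-stimulus samples.  Noise is i.i.d. over channels and
#' samples.  The noise-free per-source channel data and the noise itself
#' are returned as the truth side-channel.
#'
#' @param model a [make_default_sources()] model.
#' @param n_subjects number of simulated subjects (>= 1).
#' @return list with `data` (an [erp_dataset]), `truth` (list of 4-D
#'   per-source arrays), `noise` (4-D array) and `jitter` (per-subject
#'   draws).
#' @export
simulate_dataset <- function(model, n_subjects) {
  stopifnot(inherits(model, "source_model"), n_subjects >= 1)
  set.seed(model$seed)
  times <- model$times
  n_ch <- model$n_channels
  n_t <- length(times)
  src_names <- names(model$sources)
  truth <- lapply(src_names, function(nm) array(0, c(n_subjects, 1L, n_ch, n_t)))
  names(truth) <- src_names
  mixed <- array(0, c(n_subjects, 1L, n_ch, n_t))
  jitter <- list(shift = matrix(0, n_subjects, length(src_names),
                                dimnames = list(NULL, src_names)),
                 scale = matrix(1, n_subjects, length(src_names),
                                dimnames = list(NULL, src_names)))
  for (s in seq_len(n_subjects)) {
    for (nm in src_names) {
      src <- model$sources[[nm]]
      shift <- 0; scale <- 1
      if (nm %in% model$jittered_sources) {
        shift <- stats::rnorm(1L, 0, model$latency_jitter_sd)
        scale <- max(stats::rnorm(1L, 1, model$amplitude_jitter_sd), 0.1)
      }
      jitter$shift[s, nm] <- shift
      jitter$scale[s, nm] <- scale
      w <- src$polarity * src$amplitude_uv *
        .hann_lobe(times - shift, src$peak_ms, src$width_ms)
      field <- outer(src$topography, scale * w)          # channels x time
      truth[[nm]][s, 1L, , ] <- field
      mixed[s, 1L, , ] <- mixed[s, 1L, , ] + field
    }
  }
  noise <- array(0, dim(mixed))
  if (!is.na(model$snr_db)) {
    post <- times >= 0
    for (s in seq_len(n_subjects)) {
      p_sig <- mean(mixed[s, 1L, , post]^2)
      if (p_sig == 0) stop("signal power is zero; cannot calibrate SNR")
      sigma <- sqrt(p_sig / 10^(model$snr_db / 10))
      noise[s, 1L, , ] <- stats::rnorm(n_ch * n_t, 0, sigma)
    }
  }
  data <- erp_dataset(mixed + noise, times, model$srate,
                      model$montage$label[seq_len(n_ch)])
  list(data = data, truth = truth, noise = noise, jitter = jitter,
       model = model)
}

#' Empirical SNR of a noisy dataset against its noise-free truth
#'
#' Returns `10 log10(sum(truth^2) / sum((noisy - truth)^2))` over
#' post-stimulus samples; `Inf` when the residual is exactly zero.
#'
#' @param noisy,truth [erp_dataset]s (or bare arrays) of identical shape;
#'   `truth` must carry signal.
#' @param times time axis (taken from `noisy` when it is an `erp_dataset`).
#' @return SNR in dB.
#' @export
measured_snr <- function(noisy, truth, times = NULL) {
  if (inherits(noisy, "erp_dataset")) {
    times <- noisy$times
    noisy <- noisy$data
  }
  if (inherits(truth, "erp_dataset")) truth <- truth$data
  stopifnot(identical(dim(noisy), dim(truth)))
  if (is.null(times)) stop("times required when passing bare arrays")
  post <- times >= 0
  nd <- length(dim(truth))
  idx <- slice.index(truth, nd)
  p_sig <- sum(truth[post[idx]]^2)
  if (p_sig == 0) stop("truth signal power is zero")
  p_res <- sum((noisy[post[idx]] - truth[post[idx]])^2)
  if (p_res == 0) return(Inf)
  10 * log10(p_sig / p_res)
}

#' Peak latency of a trace by quadratic interpolation
#'
#' Locates the extremum of `polarity * trace` inside `window` and refines
#' it with a three-point parabolic fit, giving sub-sample latency estimates
#' for the jitter-recovery checks.
#'
#' @param trace numeric vector over `times`.
#' @param times time axis, ms.
#' @param window search window, ms pair.
#' @param polarity `+1` to locate a maximum, `-1` a minimum.
#' @return latency in ms.
#' @export
fit_peak_latency <- function(trace, times, window, polarity = 1) {
  sel <- which(times >= window[1L] & times <= window[2L])
  y <- polarity * trace[sel]
  i <- which.max(y)
  k <- sel[i]
  if (i == 1L || i == length(sel)) return(times[k])
  y0 <- polarity * trace[k - 1L]; y1 <- polarity * trace[k]
  y2 <- polarity * trace[k + 1L]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) < 1e-15) 0 else 0.5 * (y0 - y2) / denom
  times[k] + delta * (times[2L] - times[1L])
}
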