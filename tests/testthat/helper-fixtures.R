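# shared fixtures: everything is generated in code, no data files

default_times <- function(srate = 150, window = c(-200, 800)) {
  window[1L] + (0:round(diff(window) / 1000 * srate)) * 1000 / srate
}

# single-trace erp_dataset wrapper
trace_dataset <- function(v, srate = 150, label = "Cz",
                          times = default_times(srate)) {
  erp_dataset(array(v, c(1L, 1L, 1L, length(v))), times, srate, label)
}

# small multi-subject simulation (cached per parameter set within a run)
small_sim <- local({
  cache <- list()
  function(n = 10L, snr = 10, seed = 3L) {
    key <- paste(n, snr, seed)
    if (is.null(cache[[key]])) {
      model <- make_default_sources(snr_db = snr, seed = seed)
      cache[[key]] <<- list(model = model,
                            sim = simulate_dataset(model, n))
    }
    cache[[key]]
  }
})

# synthetic time-frequency image: Gaussian blobs on a log frequency grid
blob_image <- function(blobs, n_f = 30L, n_t = 151L, fmin = 1, fmax = 15,
                       times = default_times()) {
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_f))
  v <- matrix(0, n_f, n_t)
  for (b in blobs) {
    v <- v + b$amp * outer(exp(-((freqs - b$f0) / b$fsd)^2),
                           exp(-((times - b$t0) / b$tsd)^2))
  }
  structure(list(values = v, freqs = freqs, times = times,
                 electrodes = "Cz"), class = "tfr_image")
}

# selection criteria used for the two target oscillations
n2_criteria <- function(min_similarity = 0.35) {
  selection_criteria(-1, c(260, 400), c("FCz", "FC1", "FC2", "Fz", "Cz"),
                     min_similarity)
}
p3_criteria <- function(min_similarity = 0.35) {
  selection_criteria(+1, c(370, 580), c("Cz", "C1", "C2", "CPz", "FCz"),
                     min_similarity)
}
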