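#' Write an ERP dataset to a hierarchical directory archive
#'
#' Plain-text stand-in for an HDF5-style archive: the directory holds
#' `meta.json` (srate, axis labels, times), `data.tsv` (one row per
#' subject/condition/channel, one column per sample), and optionally
#' `truth/<source>.tsv` plus `noise.tsv` with the same row layout.  Values
#' round-trip losslessly (full double precision).
#'
#' @param data an [erp_dataset].
#' @param path archive directory (created if needed).
#' @param truth optional named list of per-source truth arrays.
#' @param noise optional noise array.
#' @export
write_erp_archive <- function(data, path, truth = NULL, noise = NULL) {
  stopifnot(inherits(data, "erp_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(srate = data$srate, times = data$times,
               channels = data$channel_labels,
               conditions = data$condition_labels,
               subjects = data$subject_ids,
               sources = names(truth))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flatten <- function(arr) {
    d <- dim(arr)
    out <- matrix(0, d[1L] * d[2L] * d[3L], d[4L])
    row <- 1L
    for (s in seq_len(d[1L])) for (co in seq_len(d[2L])) {
      out[row:(row + d[3L] - 1L), ] <- arr[s, co, , ]
      row <- row + d[3L]
    }
    out
  }
  wr <- function(m, f) {
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       f, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  wr(flatten(data$data), file.path(path, "data.tsv"))
  if (!is.null(truth)) {
    dir.create(file.path(path, "truth"), showWarnings = FALSE)
    for (nm in names(truth)) {
      wr(flatten(truth[[nm]]), file.path(path, "truth", paste0(nm, ".tsv")))
    }
  }
  if (!is.null(noise)) wr(flatten(noise), file.path(path, "noise.tsv"))
  invisible(path)
}

#' Read an ERP archive written by [write_erp_archive()]
#'
#' @param path archive directory.
#' @return list with `data` (an [erp_dataset]), `truth` (named list or
#'   `NULL`), `noise` (array or `NULL`).
#' @export
read_erp_archive <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  n_s <- length(meta$subjects); n_c <- length(meta$conditions)
  n_ch <- length(meta$channels); n_t <- length(meta$times)
  unflatten <- function(m) {
    arr <- array(0, c(n_s, n_c, n_ch, n_t))
    row <- 1L
    for (s in seq_len(n_s)) for (co in seq_len(n_c)) {
      arr[s, co, , ] <- m[row:(row + n_ch - 1L), ]
      row <- row + n_ch
    }
    arr
  }
  rd <- function(f) as.matrix(utils::read.table(f, sep = "\t"))
  data <- erp_dataset(unflatten(rd(file.path(path, "data.tsv"))),
                      meta$times, meta$srate, meta$channels,
                      meta$conditions, meta$subjects)
  truth <- NULL
  if (length(meta$sources)) {
    truth <- lapply(meta$sources, function(nm) {
      unflatten(rd(file.path(path, "truth", paste0(nm, ".tsv"))))
    })
    names(truth) <- meta$sources
  }
  noise_file <- file.path(path, "noise.tsv")
  noise <- if (file.exists(noise_file)) unflatten(rd(noise_file)) else NULL
  list(data = data, truth = truth, noise = noise)
}
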