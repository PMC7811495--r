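#' Standard 65-channel montage
#'
#' A 10-20/10-10 style 65-electrode layout with schematic 2-D head
#' coordinates (anterior positive y, left negative x, arbitrary grid units).
#' The coordinates drive the spatial Gaussian topographies of the synthetic
#' sources; they are schematic, not digitised positions.
#'
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
default_montage <- function() {
  rows <- list(
    list(y =  4, labels = c("Fp1", "Fpz", "Fp2"), x = c(-1, 0, 1)),
    list(y =  3, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
         x = c(-3, -1.5, 0, 1.5, 3)),
    list(y =  2, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         x = -4:4),
    list(y =  1, labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                            "FC6", "FT8"), x = -4:4),
    list(y =  0, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                            "T8"), x = -4:4),
    list(y = -1, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                            "CP6", "TP8"), x = -4:4),
    list(y = -2, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
                            "P8"), x = -4:4),
    list(y = -3, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
         x = c(-3, -1.5, 0, 1.5, 3)),
    list(y = -4, labels = c("O1", "Oz", "O2"), x = c(-1, 0, 1)),
    list(y = -1, labels = c("TP9", "TP10"), x = c(-5, 5)),
    list(y = -2, labels = c("P9", "P10"), x = c(-5, 5))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r$labels, x = r$x, y = r$y, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Gaussian scalp topography centred on a channel; unit magnitude at centre
.gaussian_topography <- function(montage, peak_channel, sigma = 1.6) {
  i <- match(peak_channel, montage$label)
  if (is.na(i)) stop("unknown channel: ", peak_channel)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  exp(-d2 / (2 * sigma^2))
}
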