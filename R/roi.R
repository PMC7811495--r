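#' Canny detector parameters
#'
#' @param gaussian_sigma smoothing SD in pixels (default `sqrt(2)`); the
#'   pixel grid is (frequency bin, time sample) with no resampling, and
#'   the smoothing is isotropic in index space.
#' @param high_quantile when thresholds are chosen from the image, `T1` is
#'   this quantile of the positive gradient magnitudes (default 0.70).
#' @param low_fraction `T2 = low_fraction * T1` (default 0.4).
#' @param t1,t2 explicit thresholds in gradient units, overriding the
#'   quantile rule; must satisfy `t2 < t1`.
#' @param closing_radius radius (in morphological iterations of a 3x3
#'   element) of the closing that bridges gaps in the detected contour
#'   before hole filling (default 6; a plain 3x3 closing never closes the
#'   ring an elongated time-frequency blob produces on a 30 x 151 grid,
#'   where low-gradient stretches leave gaps of up to ~10 pixels).
#' @return list of class `canny_params`.
#' @export
canny_params <- function(gaussian_sigma = sqrt(2), high_quantile = 0.70,
                         low_fraction = 0.4, t1 = NULL, t2 = NULL,
                         closing_radius = 6L) {
  if (!is.null(t1) && !is.null(t2) && t2 >= t1) stop("need t2 < t1")
  structure(list(gaussian_sigma = gaussian_sigma,
                 high_quantile = high_quantile, low_fraction = low_fraction,
                 t1 = t1, t2 = t2, closing_radius = as.integer(closing_radius)),
            class = "canny_params")
}

# separable Gaussian smoothing with replicated edges
.gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    ext <- m[c(rep(1L, half), seq_len(n), rep(n, half)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * ext[(i - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Image gradient by central differences
#'
#' `Gx` differentiates along columns (time axis), `Gy` along rows
#' (frequency axis); one-sided differences at the borders.  The magnitude
#' is `sqrt(Gx^2 + Gy^2)` and the direction `atan2(Gy, Gx)`.
#'
#' @param img numeric matrix.
#' @return list with `gx`, `gy`, `magnitude`, `direction`.
#' @export
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 3L) gx[, 2:(nc - 1L)] <- (img[, 3:nc] - img[, 1:(nc - 2L)]) / 2
  gx[, 1L] <- img[, 2L] - img[, 1L]
  gx[, nc] <- img[, nc] - img[, nc - 1L]
  if (nr >= 3L) gy[2:(nr - 1L), ] <- (img[3:nr, ] - img[1:(nr - 2L), ]) / 2
  gy[1L, ] <- img[2L, ] - img[1L, ]
  gy[nr, ] <- img[nr, ] - img[nr - 1L, ]
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
       direction = atan2(gy, gx))
}

# non-maximum suppression: interpolate the two neighbours along the
# gradient direction and keep only local maxima of the magnitude
.nonmax_suppress <- function(mag, gx, gy) {
  nr <- nrow(mag); nc <- ncol(mag)
  out <- matrix(0, nr, nc)
  for (i in 2:(nr - 1L)) for (j in 2:(nc - 1L)) {
    m <- mag[i, j]
    if (m == 0) next
    ax <- abs(gx[i, j]); ay <- abs(gy[i, j])
    if (ax >= ay) {                      # mostly horizontal gradient
      w <- if (ax == 0) 0 else ay / ax
      s <- if (sign(gx[i, j]) * sign(gy[i, j]) >= 0) 1L else -1L
      m1 <- (1 - w) * mag[i, j + 1L] + w * mag[i + s, j + 1L]
      m2 <- (1 - w) * mag[i, j - 1L] + w * mag[i - s, j - 1L]
    } else {
      w <- ax / ay
      s <- if (sign(gx[i, j]) * sign(gy[i, j]) >= 0) 1L else -1L
      m1 <- (1 - w) * mag[i + 1L, j] + w * mag[i + 1L, j + s]
      m2 <- (1 - w) * mag[i - 1L, j] + w * mag[i - 1L, j - s]
    }
    if (m >= m1 && m > m2) out[i, j] <- m   # > on one side thins ties
  }
  out
}

# hysteresis: strong pixels seed a flood over 8-connected weak pixels
.hysteresis <- function(nms, t1, t2) {
  strong <- nms > t1
  weak <- nms > t2
  if (!any(strong)) return(matrix(FALSE, nrow(nms), ncol(nms)))
  lab <- .label_components(weak, connectivity = 8L)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0L]
  lab %in% keep & weak
}

# connected-component labelling by BFS; connectivity 4 or 8
.label_components <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  } else {
    di <- rep(c(-1L, 0L, 1L), 3L); dj <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(di == 0L & dj == 0L); di <- di[keep]; dj <- dj[keep]
  }
  cur <- 0L
  queue <- integer(nr * nc)
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    qh <- 1L; qt <- 1L
    queue[1L] <- start
    lab[start] <- cur
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (k in seq_along(di)) {
        ii <- i + di[k]; jj <- j + dj[k]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          q <- ii + nr * (jj - 1L)
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            qt <- qt + 1L
            queue[qt] <- q
          }
        }
      }
    }
  }
  lab
}

.dilate3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1L, 1L + di):min(nr, nr + di)
    ti <- max(1L, 1L - di):min(nr, nr - di)
    sj <- max(1L, 1L + dj):min(nc, nc + dj)
    tj <- max(1L, 1L - dj):min(nc, nc - dj)
    out[ti, tj] <- out[ti, tj] | mask[si, sj]
  }
  out
}

.erode3 <- function(mask) !.dilate3(!mask)

# fill holes: background flood from the border; unreached background is hole
.fill_holes <- function(mask) {
  bg <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- .label_components(bg, connectivity = 4L)
  border_labs <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  border_labs <- border_labs[border_labs > 0L]
  mask | (bg & !(lab %in% border_labs))
}

#' Canny edge detection on a time-frequency image
#'
#' Gaussian smoothing, central-difference gradient magnitude and
#' direction, non-maximum suppression with linear interpolation along the
#' gradient direction, and two-threshold hysteresis (pixels above `T1`
#' seed edges extended through 8-connected pixels above `T2`).  Thresholds
#' default to a per-image quantile of the positive gradient magnitudes.
#' Invariant to adding a constant to the image; a constant image yields no
#' edges.
#'
#' @param img a `tfr_image` (or bare numeric matrix).
#' @param params a [canny_params()].
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, params = canny_params()) {
  m <- if (inherits(img, "tfr_image")) img$values else as.matrix(img)
  if (nrow(m) < 8L || ncol(m) < 8L) stop("image too small (need >= 8 x 8)")
  sm <- .gaussian_smooth(m, params$gaussian_sigma)
  gr <- image_gradient(sm)
  nms <- .nonmax_suppress(gr$magnitude, gr$gx, gr$gy)
  pos <- nms[nms > 0]
  if (length(pos) == 0L) return(matrix(FALSE, nrow(m), ncol(m)))
  t1 <- if (!is.null(params$t1)) params$t1
        else stats::quantile(pos, params$high_quantile, names = FALSE)
  t2 <- if (!is.null(params$t2)) params$t2 else params$low_fraction * t1
  .hysteresis(nms, t1, t2)
}

#' Delineate an oscillation region on a TFR image
#'
#' Canny edges are closed morphologically (3x3 closing), holes are filled,
#' and the 4-connected filled component containing the image maximum
#' inside the frequency band of interest becomes the region mask
#' (boundary pixels included).  Per-subject/condition mean power over the
#' masked pixels is reported when a `tfr_set` is supplied.
#'
#' @param img a `tfr_image`.
#' @param band Hz pair: the frequency band of interest.
#' @param params a [canny_params()].
#' @param tfrs optional `tfr_set` from which per-subject region means are
#'   computed with the group-level mask.
#' @param peak_window ms pair restricting where the in-band maximum is
#'   sought (default post-stimulus).
#' @return object of class `ero_region`: `mask`, `boundary`, `method`,
#'   `band`, `freqs`, `times`, and `means` (subject x condition matrix,
#'   when `tfrs` given).  Raises a `no_region_found` condition when no
#'   filled component contains the in-band maximum.
#' @export
extract_region <- function(img, band, params = canny_params(), tfrs = NULL,
                           peak_window = c(0, Inf)) {
  stopifnot(inherits(img, "tfr_image"))
  # pad the frequency axis with zero rows: baseline-corrected power decays
  # to ~0 off the oscillation, so a blob clipped by the frequency limits
  # (delta activity reaching below the lowest analysed bin) still forms a
  # closed contour against the padding; the time axis is left alone
  mar <- params$closing_radius + 3L
  nr <- nrow(img$values); nc <- ncol(img$values)
  padded <- rbind(matrix(0, mar, nc), img$values, matrix(0, mar, nc))
  edges <- canny_edges(padded, params)
  closed <- edges
  for (i in seq_len(params$closing_radius)) closed <- .dilate3(closed)
  for (i in seq_len(params$closing_radius)) closed <- .erode3(closed)
  filled <- .fill_holes(closed | edges)
  lab <- .label_components(filled, connectivity = 4L)
  lab <- lab[mar + seq_len(nr), , drop = FALSE]
  inband <- which(img$freqs >= band[1L] & img$freqs <= band[2L])
  if (length(inband) == 0L) stop("band outside frequency axis")
  # the in-band maximum is sought post-stimulus by default (evoked
  # responses live there; pre-stimulus/edge pixels stay maskable)
  tsel <- which(img$times >= peak_window[1L] & img$times <= peak_window[2L])
  sub <- img$values[inband, tsel, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  pk_i <- inband[pk[1L]]; pk_j <- tsel[pk[2L]]
  if (lab[pk_i, pk_j] == 0L) {
    stop(structure(class = c("no_region_found", "error", "condition"),
                   list(message = sprintf(
                     "no closed region contains the in-band (%g-%g Hz) maximum",
                     band[1L], band[2L]), call = sys.call())))
  }
  mask <- lab == lab[pk_i, pk_j]
  region_from_mask(mask, img, tfrs, method = "edge", band = band,
                   boundary = mask & !.erode3(mask))
}

#' Conventional rectangle region
#'
#' The mask is every (frequency, time) bin inside the closed rectangle
#' `freq` x `time`; region means as in [extract_region()].
#'
#' @param img a `tfr_image` (defines the axes and the grand-average
#'   values).
#' @param time ms pair.
#' @param freq Hz pair.
#' @param tfrs optional `tfr_set` for per-subject means.
#' @return an `ero_region` with `method = "rectangle"`.
#' @export
rectangle_region <- function(img, time, freq, tfrs = NULL) {
  stopifnot(inherits(img, "tfr_image"))
  fi <- img$freqs >= freq[1L] & img$freqs <= freq[2L]
  ti <- img$times >= time[1L] & img$times <= time[2L]
  if (!any(fi) || !any(ti)) stop("empty rectangle window")
  mask <- outer(fi, ti, `&`)
  region_from_mask(mask, img, tfrs, method = "rectangle",
                   rect = list(time = time, freq = freq))
}

#' Region object from an explicit mask
#'
#' The region-mean power of a subject/condition is the mean of its TFR
#' over the masked pixels (the group-level mask is applied to every
#' subject).
#'
#' @param mask logical freqs-by-time matrix.
#' @param img the `tfr_image` supplying axes and grand-average values.
#' @param tfrs optional `tfr_set` for per-subject means.
#' @param method,band,rect,boundary metadata stored on the result.
#' @return an `ero_region`.
#' @export
region_from_mask <- function(mask, img, tfrs = NULL, method = "mask",
                             band = NULL, rect = NULL, boundary = NULL) {
  stopifnot(all(dim(mask) == dim(img$values)))
  means <- NULL
  if (!is.null(tfrs)) {
    ch <- match(img$electrodes, tfrs$channel_labels)
    if (anyNA(ch)) stop("image electrodes missing from tfr_set")
    d <- dim(tfrs$power)
    means <- matrix(0, d[1L], d[2L],
                    dimnames = list(tfrs$subject_ids, tfrs$condition_labels))
    idx <- which(mask)
    for (s in seq_len(d[1L])) for (co in seq_len(d[2L])) {
      m <- apply(tfrs$power[s, co, ch, , , drop = FALSE], c(4L, 5L), mean)
      means[s, co] <- mean(m[idx])
    }
  }
  structure(list(mask = mask, boundary = boundary, method = method,
                 band = band, rect = rect, freqs = img$freqs,
                 times = img$times, electrodes = img$electrodes,
                 grand_mean = mean(img$values[mask]), means = means),
            class = "ero_region")
}

#' @export
print.ero_region <- function(x, ...) {
  cat(sprintf("<ero_region> method=%s, %d/%d pixels, grand mean %.4g\n",
              x$method, sum(x$mask), length(x$mask), x$grand_mean))
  invisible(x)
}

#' Count distinct oscillation regions across frequency bands
#'
#' Runs the edge-detection region extraction once per band on one or more
#' images and counts how many distinct filled components are hit (two
#' bands landing in the same component count once; a band with no region
#' contributes nothing).
#'
#' @param imgs a `tfr_image` or list of them (one per band, recycled).
#' @param bands list of Hz pairs.
#' @param params a [canny_params()].
#' @return integer count of distinct regions.
#' @export
count_ero_regions <- function(imgs, bands, params = canny_params()) {
  if (inherits(imgs, "tfr_image")) imgs <- list(imgs)
  imgs <- rep_len(imgs, length(bands))
  img_id <- integer(length(imgs))
  seen <- list()
  for (i in seq_along(imgs)) {
    hit <- which(vapply(seen, identical, logical(1), imgs[[i]]))
    if (length(hit)) img_id[i] <- hit[1L]
    else { seen <- c(seen, list(imgs[[i]])); img_id[i] <- length(seen) }
  }
  keys <- character(0)
  for (i in seq_along(bands)) {
    reg <- tryCatch(extract_region(imgs[[i]], bands[[i]], params),
                    no_region_found = function(e) NULL)
    if (!is.null(reg)) {
      keys <- c(keys, paste0(img_id[i], ":",
                             paste(which(reg$mask), collapse = ",")))
    }
  }
  length(unique(keys))
}
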