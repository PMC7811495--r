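#' Stack an ERP dataset into the observations-by-time matrix
#'
#' Rows are subject-major, then condition, then channel; columns are the
#' time samples inside `time_window` (right-open, `lo <= t < hi`; pass
#' `NULL` for the full epoch).  Column means are recorded so the centred
#' decomposition can be undone.
#'
#' @param data an [erp_dataset].
#' @param time_window ms pair or `NULL`.
#' @return object of class `erp_matrix`: `Z` (N x M), `row_index`
#'   (data.frame subject/condition/channel per row), `column_means`,
#'   `times`, `srate`, plus the axis labels.
#' @export
build_matrix <- function(data, time_window = NULL) {
  stopifnot(inherits(data, "erp_dataset"))
  d <- dim(data$data)
  if (is.null(time_window)) {
    sel <- seq_along(data$times)
  } else {
    sel <- which(data$times >= time_window[1L] & data$times < time_window[2L])
  }
  n_s <- d[1L]; n_c <- d[2L]; n_ch <- d[3L]
  # subject-major, then condition, then channel
  ri <- expand.grid(channel = seq_len(n_ch), condition = seq_len(n_c),
                    subject = seq_len(n_s))[, 3:1]
  Z <- matrix(0, n_s * n_c * n_ch, length(sel))
  row <- 1L
  for (s in seq_len(n_s)) for (co in seq_len(n_c)) {
    Z[row:(row + n_ch - 1L), ] <- data$data[s, co, , sel]
    row <- row + n_ch
  }
  structure(list(Z = Z, row_index = ri,
                 column_means = colMeans(Z),
                 times = data$times[sel], srate = data$srate,
                 dims = c(subjects = n_s, conditions = n_c, channels = n_ch),
                 channel_labels = data$channel_labels,
                 condition_labels = data$condition_labels,
                 subject_ids = data$subject_ids),
            class = "erp_matrix")
}

#' Number of components retained at a cumulative-variance threshold
#'
#' Smallest `R` with `sum(lambda[1:R]) / sum(lambda) >= threshold`
#' (inclusive at exact equality).
#'
#' @param eigenvalues non-increasing non-negative variances.
#' @param threshold fraction in (0, 1].
#' @return integer count.
#' @export
retained_count <- function(eigenvalues, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  which(cum >= threshold - 1e-12)[1L]
}

# Promax: Varimax followed by an oblique least-squares rotation towards the
# element-wise kappa-power target (signs preserved).  Kaiser row
# normalization is optional; on covariance-scaled temporal loadings it
# destabilises the simple-structure solution, so temporal PCA disables it.
.promax <- function(loadings, kappa = 3, kaiser = FALSE) {
  vm <- stats::varimax(loadings, normalize = kaiser)
  A <- loadings %*% vm$rotmat
  P <- abs(A)^kappa * sign(A)
  Q <- solve(crossprod(A), crossprod(A, P))
  d <- diag(solve(crossprod(Q)))
  Q <- Q %*% diag(sqrt(d), ncol(Q))         # unit-variance factor scaling
  pattern <- A %*% Q
  phi <- solve(crossprod(Q))
  list(pattern = pattern, rotmat = vm$rotmat %*% Q, phi = phi)
}

#' Temporal PCA with Promax rotation
#'
#' Columns of `Z` (time samples) are mean-centred; an SVD-based PCA
#' retains the smallest component count reaching `variance_threshold`
#' cumulative explained variance; the retained loadings (scaled by their
#' singular values) are rotated with Kaiser-normalised Varimax followed by
#' Promax with power `kappa`.  Scores are computed so that
#' `scores %*% t(pattern)` equals the centred data's projection onto the
#' retained subspace (and, over all components, reconstructs the centred
#' data).
#'
#' @param Z an [erp_matrix] from [build_matrix()].
#' @param variance_threshold cumulative explained-variance fraction
#'   (default 0.99).
#' @param kappa Promax power (default 3; typical range 2--4).
#' @param kaiser apply Kaiser row normalization in the Varimax step
#'   (default `FALSE`; see the methods vignette for why temporal PCA
#'   disables it while the TFA-PCA comparator keeps it).
#' @param min_components optional floor on the retained count: at high SNR
#'   the cumulative-variance rule can retain too few components for the
#'   rotation to give each overlapping source its own component(s);
#'   liberal retention is standard ERP-PCA practice.  `NULL` disables the
#'   floor.
#' @return object of class `decomposition` with unrotated/rotated
#'   loadings, scores, eigenvalues, per-component explained variance
#'   percentages, the factor correlation matrix and metadata.
#' @export
tpca <- function(Z, variance_threshold = 0.99, kappa = 3, kaiser = FALSE,
                 min_components = NULL) {
  stopifnot(inherits(Z, "erp_matrix"))
  Zc <- sweep(Z$Z, 2L, Z$column_means)
  n <- nrow(Zc)
  sv <- svd(Zc)
  eigenvalues <- sv$d^2 / (n - 1)
  expl_pct <- 100 * eigenvalues / sum(eigenvalues)
  R <- if (variance_threshold >= 1) length(eigenvalues)   # keep everything
       else retained_count(eigenvalues, variance_threshold)
  if (!is.null(min_components)) R <- max(R, as.integer(min_components))
  rank_eff <- sum(sv$d > sv$d[1L] * 1e-14)
  if (R > rank_eff) {
    warning("rank-deficient data: reducing R from ", R, " to ", rank_eff)
    R <- rank_eff
  }
  V <- sv$v[, seq_len(R), drop = FALSE]
  dvals <- sv$d[seq_len(R)]
  loadings <- V %*% diag(dvals / sqrt(n - 1), R)   # scaled (covariance) loadings
  # rotate only components carrying non-negligible variance; near-null
  # directions (possible when the threshold is 1 on band-limited data)
  # pass through unrotated so the oblique system stays well conditioned
  R_rot <- sum(eigenvalues[seq_len(R)] >= 1e-6 * eigenvalues[1L])
  pattern <- loadings
  phi <- diag(1, R)
  pv <- diag(dvals / sqrt(n - 1), R)                # pattern = V %*% pv
  if (R_rot > 1L) {
    pm <- .promax(loadings[, seq_len(R_rot), drop = FALSE], kappa, kaiser)
    pattern[, seq_len(R_rot)] <- pm$pattern
    phi[seq_len(R_rot), seq_len(R_rot)] <- pm$phi
    pv[seq_len(R_rot), seq_len(R_rot)] <-
      pv[seq_len(R_rot), seq_len(R_rot), drop = FALSE] %*% pm$rotmat
  }
  scores <- Zc %*% V %*% t(solve(pv))
  structure(list(
    loadings_unrotated = V,
    loadings = pattern,
    scores = scores,
    eigenvalues = eigenvalues,
    explained_variance_pct = expl_pct,
    factor_correlation = phi,
    R = R,
    kappa = kappa,
    variance_threshold = variance_threshold,
    row_index = Z$row_index,
    dims = Z$dims,
    column_means = Z$column_means,
    times = Z$times, srate = Z$srate,
    channel_labels = Z$channel_labels,
    condition_labels = Z$condition_labels,
    subject_ids = Z$subject_ids
  ), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> R = %d components (%.2f%% variance), kappa = %g\n",
              x$R, sum(x$explained_variance_pct[seq_len(x$R)]), x$kappa))
  invisible(x)
}

# per-subject topographies of one component: its scores reshaped over
# channels, averaged over conditions -> subjects x channels
.component_topographies <- function(dec, comp) {
  sc <- dec$scores[, comp]
  d <- dec$dims
  arr <- array(sc, c(d["channels"], d["conditions"], d["subjects"]))
  t(apply(arr, 3L, function(m) rowMeans(matrix(m, nrow = d["channels"]))))
}

#' Pairwise spatial similarity of subject topographies
#'
#' Mean and SD of the Pearson correlations between all subject pairs'
#' topographies (the homogeneity criterion for component selection).
#' Zero-variance topographies are excluded from the pairing with a
#' warning.
#'
#' @param topographies `subjects x channels` matrix.
#' @return list with `mean`, `sd` and `n_pairs`.
#' @export
spatial_similarity <- function(topographies) {
  stopifnot(nrow(topographies) >= 2L)
  sds <- apply(topographies, 1L, stats::sd)
  ok <- which(sds > 0)
  if (length(ok) < nrow(topographies)) {
    warning("excluding ", nrow(topographies) - length(ok),
            " zero-variance topographies")
  }
  if (length(ok) < 2L) stop("fewer than two usable topographies")
  cm <- stats::cor(t(topographies[ok, , drop = FALSE]))
  rs <- cm[upper.tri(cm)]
  list(mean = mean(rs), sd = stats::sd(rs), n_pairs = length(rs))
}

#' Component-selection criteria
#'
#' @param polarity expected scalp polarity of the deflection (+1/-1).
#' @param latency_window ms window that must contain the dominant peak of
#'   the temporal loading.
#' @param channels channel labels forming the admissible peak region of the
#'   mean subject topography.
#' @param min_similarity minimum mean pairwise spatial similarity
#'   (default 0.4).
#' @return list of class `selection_criteria`.
#' @export
selection_criteria <- function(polarity, latency_window, channels,
                               min_similarity = 0.4) {
  structure(list(polarity = polarity, latency_window = latency_window,
                 channels = channels, min_similarity = min_similarity),
            class = "selection_criteria")
}

#' Automated component shortlist
#'
#' A component is shortlisted when (a) the dominant peak of its temporal
#' loading falls inside the latency window with the required joint
#' polarity (sign of loading peak times sign of the mean topography in the
#' admissible region -- invariant to the component's sign
#' indeterminacy), (b) the peak of the absolute mean subject topography
#' lies in the admissible channel region, and (c) the mean pairwise
#' spatial similarity reaches the threshold.
#'
#' @param dec a [tpca()] decomposition.
#' @param criteria a [selection_criteria()].
#' @param manual optional integer indices overriding the automated rule
#'   (logged in the result).
#' @return object of class `component_selection`: `selected`,
#'   per-component `similarity` (mean/sd), `detail` data.frame, and the
#'   criteria used.
#' @export
select_components <- function(dec, criteria, manual = NULL) {
  stopifnot(inherits(dec, "decomposition"))
  chan_idx <- match(criteria$channels, dec$channel_labels)
  if (anyNA(chan_idx)) stop("unknown channel in criteria")
  detail <- data.frame(component = seq_len(dec$R), peak_ms = NA_real_,
                       peak_channel = NA_character_, polarity = NA_real_,
                       similarity_mean = NA_real_, similarity_sd = NA_real_,
                       selected = FALSE)
  for (r in seq_len(dec$R)) {
    load <- dec$loadings[, r]
    pk <- which.max(abs(load))
    topo <- .component_topographies(dec, r)
    tbar <- colMeans(topo)
    sim <- spatial_similarity(topo)
    pol <- sign(load[pk]) * sign(mean(tbar[chan_idx]))
    detail$peak_ms[r] <- dec$times[pk]
    detail$peak_channel[r] <- dec$channel_labels[which.max(abs(tbar))]
    detail$polarity[r] <- pol
    detail$similarity_mean[r] <- sim$mean
    detail$similarity_sd[r] <- sim$sd
    detail$selected[r] <-
      dec$times[pk] >= criteria$latency_window[1L] &&
      dec$times[pk] <= criteria$latency_window[2L] &&
      pol == criteria$polarity &&
      detail$peak_channel[r] %in% criteria$channels &&
      sim$mean >= criteria$min_similarity
  }
  selected <- which(detail$selected)
  if (!is.null(manual)) {
    selected <- sort(unique(as.integer(manual)))
    detail$selected <- detail$component %in% selected
  }
  if (length(selected) == 0L) warning("no components matched the criteria")
  structure(list(selected = selected, detail = detail, criteria = criteria,
                 manual = !is.null(manual)),
            class = "component_selection")
}

#' Back-project selected components to the electrode fields
#'
#' Computes `scores[, S] %*% t(pattern[, S])` and reshapes the rows back to
#' the `subjects x conditions x channels x time` layout.  Column means are
#' re-added only when every component is selected (a partial selection is
#' component-specific activity, for which the grand mean is undefined).
#' The result is invariant under a simultaneous sign flip of any selected
#' component's loading and score columns.
#'
#' @param dec a [tpca()] decomposition.
#' @param selection a [component_selection] or integer component indices.
#' @return an [erp_dataset] holding the virtual (back-projected) ERP.
#' @export
back_project <- function(dec, selection) {
  stopifnot(inherits(dec, "decomposition"))
  S <- if (inherits(selection, "component_selection")) selection$selected
       else as.integer(selection)
  if (length(S) == 0L) stop("empty component selection")
  stopifnot(all(S >= 1L), all(S <= dec$R))
  Zbar <- dec$scores[, S, drop = FALSE] %*% t(dec$loadings[, S, drop = FALSE])
  full <- length(S) == dec$R &&
    sum(dec$explained_variance_pct[seq_len(dec$R)]) >= 100 - 1e-6
  if (full) {
    Zbar <- sweep(Zbar, 2L, dec$column_means, "+")
  }
  d <- dec$dims
  arr <- array(0, c(d["subjects"], d["conditions"], d["channels"],
                    ncol(Zbar)))
  row <- 1L
  for (s in seq_len(d["subjects"])) for (co in seq_len(d["conditions"])) {
    arr[s, co, , ] <- Zbar[row:(row + d["channels"] - 1L), ]
    row <- row + d["channels"]
  }
  erp_dataset(arr, dec$times, dec$srate, dec$channel_labels,
              dec$condition_labels, dec$subject_ids)
}
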