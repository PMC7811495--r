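#' Pearson product-moment correlation
#'
#' Arrays are flattened frequency-major (column order for matrices) before
#' correlating; both operands must use the same layout.  Constant input is
#' an error rather than `NA`.
#'
#' @param x,y numeric vectors/matrices/arrays of equal length (>= 3).
#' @return correlation coefficient.
#' @export
pearson <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

# Greenhouse-Geisser epsilon for a k-level within factor from the
# subjects x levels matrix (identity, epsilon = 1, when k = 2)
.gg_epsilon <- function(m) {
  k <- ncol(m)
  if (k <= 2L) return(1)
  S <- stats::cov(m)
  dbar <- mean(diag(S)); gbar <- mean(S)
  rbar <- rowMeans(S)
  num <- (k * (dbar - gbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rbar^2) + k^2 * gbar^2)
  num / den
}

#' Two-way repeated-measures ANOVA (2 x 2 within-subject design)
#'
#' Classical within-subject sums-of-squares decomposition for two 2-level
#' factors: each effect is tested against its own subject-by-effect error
#' term (`F = MS_effect / MS_error`, df = (1, n-1)); partial eta squared
#' is `SS_effect / (SS_effect + SS_error)`.  Greenhouse-Geisser epsilon is
#' reported (identically 1 for 2-level factors, so df are uncorrected in
#' this design).  When the interaction is significant at `alpha`, paired
#' t-tests of factor B within each level of A are run as simple effects
#' (uncorrected p-values).
#'
#' @param values numeric `subjects x 4` matrix; columns ordered A1B1,
#'   A1B2, A2B1, A2B2.
#' @param factor_names length-2 character, names of factors A and B.
#' @param alpha significance level gating the simple-effects tests.
#' @return object of class `anova_result`: data.frame `table` (effect, F,
#'   df1, df2, p, pes, gg_epsilon), `posthoc` (or `NULL`), `ss` (all
#'   sums of squares).
#' @export
rm_anova_2x2 <- function(values, factor_names = c("A", "B"), alpha = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) != 4L) stop("need exactly 4 condition columns")
  if (anyNA(values)) stop("missing cells are not supported")
  n <- nrow(values)
  if (n < 3L) stop("need at least 3 subjects")
  a <- matrix(c(1, 1, 2, 2), 1L)[1L, ]      # factor A level per column
  b <- c(1, 2, 1, 2)                        # factor B level per column
  grand <- mean(values)
  subj_m <- rowMeans(values)
  A_m <- vapply(1:2, function(l) mean(values[, a == l]), 0)
  B_m <- vapply(1:2, function(l) mean(values[, b == l]), 0)
  ss_subj <- 4 * sum((subj_m - grand)^2)
  ss_A <- 2 * n * sum((A_m - grand)^2)
  ss_B <- 2 * n * sum((B_m - grand)^2)
  cell_m <- vapply(1:4, function(j) mean(values[, j]), 0)
  ss_cells <- n * sum((cell_m - grand)^2)
  ss_AB <- ss_cells - ss_A - ss_B
  # subject x effect interaction error terms
  subjA <- vapply(1:2, function(l) rowMeans(values[, a == l, drop = FALSE]), numeric(n))
  subjB <- vapply(1:2, function(l) rowMeans(values[, b == l, drop = FALSE]), numeric(n))
  ss_Aerr <- 2 * sum((subjA - outer(subj_m, rep(1, 2)) -
                        outer(rep(1, n), A_m) + grand)^2)
  ss_Berr <- 2 * sum((subjB - outer(subj_m, rep(1, 2)) -
                        outer(rep(1, n), B_m) + grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_ABerr <- ss_tot - ss_subj - ss_A - ss_Aerr - ss_B - ss_Berr - ss_AB
  effects <- data.frame(
    effect = c(factor_names[1L], factor_names[2L],
               paste(factor_names, collapse = ":")),
    ss = c(ss_A, ss_B, ss_AB),
    ss_err = c(ss_Aerr, ss_Berr, ss_ABerr)
  )
  df1 <- 1L; df2 <- n - 1L
  effects$F <- (effects$ss / df1) / (effects$ss_err / df2)
  effects$F[effects$ss <= 1e-12 * max(ss_tot, 1)] <- 0   # 0/0 -> no effect
  effects$df1 <- df1; effects$df2 <- df2
  effects$p <- stats::pf(effects$F, df1, df2, lower.tail = FALSE)
  effects$pes <- effects$ss / (effects$ss + effects$ss_err)
  effects$pes[effects$ss <= 1e-12 * max(ss_tot, 1)] <- 0
  effects$gg_epsilon <- 1
  posthoc <- NULL
  if (effects$p[3L] < alpha) {
    rows <- lapply(1:2, function(l) {
      cols <- which(a == l)
      tt <- stats::t.test(values[, cols[1L]], values[, cols[2L]],
                          paired = TRUE)
      data.frame(within = paste0(factor_names[1L], l),
                 comparison = paste0(factor_names[2L], "1 vs ",
                                     factor_names[2L], "2"),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    })
    posthoc <- do.call(rbind, rows)
  }
  structure(list(
    table = effects[, c("effect", "F", "df1", "df2", "p", "pes",
                        "gg_epsilon")],
    posthoc = posthoc,
    ss = list(total = ss_tot, subjects = ss_subj, A = ss_A, A_err = ss_Aerr,
              B = ss_B, B_err = ss_Berr, AB = ss_AB, AB_err = ss_ABerr)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("simple effects:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Source-recovery correlation report
#'
#' For each source and each modality (waveform at the source's peak
#' channel, topography averaged over the source's time window, TFR image
#' at the peak channel), reports the Pearson correlations between all
#' pairs of the source truth, the mixed signal and the extracted
#' (back-projected) signal, grand-averaged across subjects.
#'
#' @param truth named list of per-source truth arrays
#'   (`[subjects, 1, channels, time]`, from [simulate_dataset()]).
#' @param extracted named list of [erp_dataset]s, one per source (the
#'   back-projections).
#' @param mixed the mixed-signal [erp_dataset].
#' @param sources data.frame with columns `source`, `peak_channel`,
#'   `win_lo`, `win_hi` (topography window, ms).
#' @param spec a [morlet_spec()] for the TFR modality.
#' @return data.frame with columns `source`, `modality`, `pair`, `r`.
#' @export
recovery_report <- function(truth, extracted, mixed, sources,
                            spec = morlet_spec()) {
  out <- list()
  times <- mixed$times
  for (k in seq_len(nrow(sources))) {
    src <- sources$source[k]
    ch <- match(sources$peak_channel[k], mixed$channel_labels)
    win <- c(sources$win_lo[k], sources$win_hi[k])
    tru_sc <- apply(truth[[src]], c(3L, 4L), mean)           # ch x time
    ext <- extracted[[src]]
    ext_sc <- apply(ext$data[, 1L, , , drop = FALSE], c(3L, 4L), mean)
    mix_sc <- apply(mixed$data[, 1L, , , drop = FALSE], c(3L, 4L), mean)
    tsel <- times >= win[1L] & times <= win[2L]
    waves <- list(source = tru_sc[ch, ], mixed = mix_sc[ch, ],
                  extracted = ext_sc[ch, ])
    topos <- list(source = rowMeans(tru_sc[, tsel, drop = FALSE]),
                  mixed = rowMeans(mix_sc[, tsel, drop = FALSE]),
                  extracted = rowMeans(ext_sc[, tsel, drop = FALSE]))
    tfr1 <- function(v) {
      ds <- erp_dataset(array(v, c(1L, 1L, 1L, length(v))), times,
                        mixed$srate, "x")
      morlet_tfr(ds, spec, baseline = FALSE)$power[1L, 1L, 1L, , ]
    }
    tfrs <- lapply(waves, tfr1)
    pairs <- list(c("source", "mixed"), c("source", "extracted"),
                  c("mixed", "extracted"))
    for (mod in c("waveform", "topography", "tfr")) {
      objs <- switch(mod, waveform = waves, topography = topos, tfr = tfrs)
      for (pr in pairs) {
        out[[length(out) + 1L]] <- data.frame(
          source = src, modality = mod,
          pair = paste(pr, collapse = "_vs_"),
          r = pearson(objs[[pr[1L]]], objs[[pr[2L]]]))
      }
    }
  }
  do.call(rbind, out)
}
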