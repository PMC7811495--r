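# Pearson recovery metrics and repeated-measures ANOVA

test_that("pearson matches the closed form and signals degenerate input", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  x <- rnorm(20)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  # invariant under positive-slope affine maps; antisymmetric under negation
  y <- rnorm(20)
  expect_equal(pearson(2 * x + 5, y), pearson(x, y))
  expect_equal(pearson(-x, y), -pearson(x, y))
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:4, 1:5), "length mismatch")
})

# independent oracle: R's aov() within-subject error decomposition
aov_oracle <- function(v) {
  df <- data.frame(y = as.vector(v),
                   s = factor(rep(seq_len(nrow(v)), 4)),
                   A = factor(rep(c(1, 1, 2, 2), each = nrow(v))),
                   B = factor(rep(c(1, 2, 1, 2), each = nrow(v))))
  fit <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = df))
  get <- function(stratum, row) {
    tab <- fit[[stratum]][[1]]
    c(F = tab[row, "F value"], p = tab[row, "Pr(>F)"],
      ss = tab[row, "Sum Sq"], ss_err = tab["Residuals", "Sum Sq"])
  }
  rbind(A = get("Error: s:A", "A"), B = get("Error: s:B", "B"),
        AB = get("Error: s:A:B", "A:B"))
}

test_that("rm-ANOVA matches the aov oracle on 50 random 21x4 tables", {
  set.seed(13)
  for (rep in 1:50) {
    v <- matrix(rnorm(21 * 4, sd = runif(1, 0.5, 3)), 21) +
      outer(rnorm(21), rep(1, 4)) +                 # subject offsets
      outer(rep(1, 21), rnorm(4))                   # condition effects
    got <- rm_anova_2x2(v)
    exp <- aov_oracle(v)
    expect_equal(got$table$F, unname(exp[, "F"]), tolerance = 1e-8)
    expect_equal(got$table$p, unname(exp[, "p"]), tolerance = 1e-8)
    pes <- exp[, "ss"] / (exp[, "ss"] + exp[, "ss_err"])
    expect_equal(got$table$pes, unname(pes), tolerance = 1e-8)
    expect_equal(got$table$df1, rep(1L, 3))
    expect_equal(got$table$df2, rep(20L, 3))
    # SS identity
    expect_equal(got$ss$total,
                 with(got$ss, subjects + A + A_err + B + B_err + AB + AB_err),
                 tolerance = 1e-9 * got$ss$total)
  }
})

test_that("degenerate tables give F = 0", {
  expect_equal(rm_anova_2x2(matrix(5, 10, 4))$table$F, rep(0, 3))
  # subject offsets only: all effect F remain 0
  v <- matrix(rep(rnorm(10), 4), 10)
  expect_equal(rm_anova_2x2(v)$table$F, rep(0, 3))
  expect_error(rm_anova_2x2(matrix(1, 2, 4)), "at least 3")
  expect_error(rm_anova_2x2(matrix(c(1, NA), 10, 4)), "missing")
})

test_that("simple effects appear only for significant interactions", {
  set.seed(14)
  v <- matrix(rnorm(21 * 4, sd = 0.2), 21)
  v[, 4] <- v[, 4] + 3                      # strong interaction + effects
  res <- rm_anova_2x2(v, factor_names = c("WT", "FB"))
  expect_false(is.null(res$posthoc))
  expect_equal(nrow(res$posthoc), 2L)
  # paired-t oracle for the first simple effect
  tt <- t.test(v[, 1], v[, 2], paired = TRUE)
  expect_equal(res$posthoc$p[1], tt$p.value, tolerance = 1e-12)
  null <- rm_anova_2x2(matrix(rnorm(84, sd = 1e-3), 21) +
                         outer(rnorm(21), rep(1, 4)))
  if (null$table$p[3] >= 0.05) expect_null(null$posthoc)
})

test_that("Greenhouse-Geisser epsilon is 1 for 2-level factors", {
  set.seed(15)
  res <- rm_anova_2x2(matrix(rnorm(84), 21))
  expect_equal(res$table$gg_epsilon, rep(1, 3))
})

test_that("recovery_report is exact when extracted equals the source", {
  obj <- small_sim(n = 4L, snr = NA, seed = 6L)
  sim <- obj$sim
  srcs <- data.frame(source = c("N2", "P3"), peak_channel = c("FCz", "Cz"),
                     win_lo = c(300, 400), win_hi = c(400, 550))
  mk <- function(arr) erp_dataset(arr, obj$model$times, 150,
                                  obj$model$montage$label)
  ext <- list(N2 = mk(sim$truth$N2), P3 = mk(sim$truth$P3))
  rep <- recovery_report(sim$truth, ext, sim$data, srcs)
  se <- rep[rep$pair == "source_vs_extracted", "r"]
  expect_equal(se, rep(1, 6), tolerance = 1e-12)
  # noise-free mixing: r(source, mixed waveform at peak channel) matches
  # the analytic mixing oracle
  iFCz <- match("FCz", obj$model$montage$label)
  mixed_w <- apply(sim$data$data[, 1, iFCz, ], 2, mean)
  src_w <- apply(sim$truth$N2[, 1, iFCz, ], 2, mean)
  want <- cor(src_w, mixed_w)
  got <- rep[rep$source == "N2" & rep$modality == "waveform" &
               rep$pair == "source_vs_mixed", "r"]
  expect_equal(got, want, tolerance = 1e-12)
})
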