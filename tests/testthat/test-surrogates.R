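# Surrogate battery: shuffling, cross-subject pairing, phase randomization,
# absolute-power control, p-value summaries, profile collapse, time scales.

test_that("shuffling destroys coupling and is seed-deterministic", {
  spec <- one_state_spec(31000, target_correlation(), seed = 31)
  sm <- smoothed_series(spec)
  rep1 <- shuffle_surrogate(sm, seed = 7)
  expect_gt(length(rep1$values) / 15, 1000)
  expect_lt(abs(mean(rep1$values)), 0.02)
  # population-z convention: null window correlations have sd ~ 1/sqrt(L)
  expect_lt(abs(sd(rep1$values) - 1 / sqrt(30)) / (1 / sqrt(30)), 0.15)
  rep2 <- shuffle_surrogate(sm, seed = 7)
  expect_identical(rep1$values, rep2$values)
  rep3 <- shuffle_surrogate(sm, seed = 8)
  expect_false(identical(rep1$values, rep3$values))

  short <- smoothed_series(one_state_spec(20, diag(6), seed = 1))
  expect_error(shuffle_surrogate(short, seed = 1), "shorter")
})

test_that("random-subject pairing never self-pairs and levels D+/D-", {
  specs <- lapply(1:4, function(k) one_state_spec(330, target_correlation(),
                                                  seed = 40 + k))
  bps <- lapply(seq_along(specs), function(k)
    smoothed_series(specs[[k]], sprintf("S%02d", k)))
  names(bps) <- sprintf("S%02d", 1:4)
  rep <- random_pair_surrogate(bps, "s1", n_realizations = 6, seed = 5)
  expect_true(all(rep$pairing_log$subject_i != rep$pairing_log$subject_j))
  expect_true(all(is.finite(as.matrix(rep$degree[, c("D_plus", "D_minus")]))))
  expect_error(random_pair_surrogate(bps[1], "s1", seed = 1), "two subjects")
  expect_error(random_pair_surrogate(bps, "s1", n_realizations = 0, seed = 1),
               "positive")
})

test_that("phase randomization preserves the amplitude spectrum and variance", {
  spec <- one_state_spec(120, target_correlation(), seed = 3,
                         sample_rate_hz = 100)
  rec <- make_protocol_recording(spec, channel_labels = c("C3", "C4"))$recording
  pr <- phase_randomize(rec, seed = 17)
  for (ch in 1:2) {
    a0 <- Mod(fft(rec$samples[ch, ]))
    a1 <- Mod(fft(pr$samples[ch, ]))
    expect_lt(max(abs(a1 - a0)) / max(a0), 1e-9)
    v0 <- var(rec$samples[ch, ])
    expect_lt(abs(var(pr$samples[ch, ]) - v0) / v0, 1e-9)
  }
  expect_true(is.numeric(pr$samples))                  # strictly real output
  expect_identical(phase_randomize(rec, seed = 17)$samples, pr$samples)
})

test_that("phase randomization collapses positive-class coupling profiles", {
  spec <- one_state_spec(1500, target_correlation(), seed = 23,
                         sample_rate_hz = 100, noise_floor = 0.05)
  rec <- make_protocol_recording(spec)$recording
  analyze <- function(r) {
    sm <- smooth_band_power(to_relative(band_power_series(r)), 14)
    degree_of_coupling(pool_values(coupling_windows(sm), "beta-gamma",
                                   state = "s1"))
  }
  orig <- analyze(rec)
  surr <- analyze(phase_randomize(rec, seed = 29))
  expect_gt(orig["D_plus"], 0.3)                       # designed coupling
  expect_lt(surr["D_plus"], orig["D_plus"] / 2)        # collapsed toward null
})

test_that("absolute power with a common trend fakes positive coupling", {
  spec <- one_state_spec(2000, target_correlation(), seed = 51)
  w <- band_weight_series(spec)
  # global multiplicative power trend shared by all bands, strong enough to
  # dominate the designed anti-correlations (the constructed confound)
  set.seed(52)
  trend <- exp(sana:::smooth_kernel(rnorm(ncol(w$values), sd = 8),
                                    sana:::gaussian_kernel(12)))
  abs_bp <- band_power(sweep(w$values, 2, trend, "*"), mode = "absolute",
                       time_s = w$time_s, channel = "SIM",
                       annotations = w$annotations)
  expect_error(absolute_power_control(abs_bp), "confirm")
  rep <- absolute_power_control(abs_bp, confirm = TRUE)
  d <- rep$degree[["s1"]]
  expect_true(all(d$D_plus[upper.tri(d$D_plus)] >
                  d$D_minus[upper.tri(d$D_minus)]))    # all 15 pairs positive
  # relative mode on the same data recovers the designed anti/positive signs
  rel <- sana(smooth_band_power(w, 14))
  dd <- rel$degree[["s1"]]
  expect_true(all(dd$D_minus[1, 2:6] > dd$D_plus[1, 2:6]))
  expect_gt(dd$D_plus[5, 6], dd$D_minus[5, 6])
})

test_that("p-value summaries count significance fractions", {
  cw <- fake_windows(C = c(0.9, 0.1, 0.85, 0.88),
                     p = c(0.01, 0.2, 0.03, 0.04))
  ps <- pvalue_summary(cw)
  expect_equal(unname(ps$pooled["frac_below"]), 0.75)
  expect_equal(unname(ps$pooled["frac_above"]), 0.25)
  # under the shuffle null p-values are uniform: ~95% above 0.05
  spec <- one_state_spec(31000, target_correlation(), seed = 31)
  rep <- shuffle_surrogate(smoothed_series(spec), seed = 7)
  psn <- pvalue_summary(rep$windows)
  expect_equal(unname(psn$pooled["frac_above"]), 0.95, tolerance = 0.015)
  expect_error(pvalue_summary(fake_windows(NaN)), "no valid")
})

test_that("profile collapse test uses the Pratt zero convention", {
  set.seed(12)
  v <- tanh(rnorm(800, 0.2, 0.5))
  g <- build_profile(v, analysis_config())
  self <- collapse_test(g, g)
  expect_equal(self$p_value, 1)
  expect_true(self$pass)

  shifted <- g
  shifted$profile <- g$profile + 0.3                   # 40 one-signed diffs
  sh <- collapse_test(shifted, g)
  expect_lt(sh$p_value, 0.05)
  expect_false(sh$pass)

  g39 <- g
  g39$bin_edges <- g$bin_edges[-1]
  expect_error(collapse_test(g39, g), "bin grids")

  # cross-check against the base signed-rank test on zero-free differences
  d <- tanh(rnorm(40, 0.05, 0.2))
  p_pratt <- sana:::wilcoxon_pratt(d)$p_value
  p_base <- wilcox.test(d, correct = TRUE)$p.value
  expect_equal(p_pratt, p_base, tolerance = 0.05)
})

test_that("time-scale sweep keeps class labels for strong coupling", {
  spec <- generator_spec(
    list(list(label = "rest",
              target_R = target_correlation(-0.35, 0.35, -0.3, -0.2),
              duration_s = 1200),
         list(label = "exercise",
              target_R = target_correlation(-0.7, 0.7, 0.5, 0.4),
              duration_s = 1200)),
    seed = 61)
  w <- band_weight_series(spec)
  expect_warning(sw <- timescale_sweep(w, corr_windows = c(20, 30, 45),
                                       smooth_windows = c(8, 14)),
                 "half the correlation window")
  expect_true(is.na(sw$classes[["L20_s14"]][1]))       # guard honored
  done <- sw$classes[!vapply(sw$classes, function(x) all(is.na(x)), TRUE)]
  expect_gte(length(done), 4)
  # delta pairs anti and sigma/beta/gamma positive at every retained setting
  for (cl in done) {
    expect_true(all(cl[1:5] == "anti"))
    expect_true(all(cl[13:15] == "positive"))
  }
})
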