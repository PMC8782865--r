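# Generator: correlated latent modulators, softmax band weights, and EEG
# synthesis with band-limited carriers.

test_that("generator spec validation rejects malformed inputs", {
  bad_R <- matrix(0.9, 6, 6); diag(bad_R) <- 1
  bad_R[1, 2] <- -0.9                                  # asymmetric
  expect_error(one_state_spec(100, bad_R), "symmetric")
  npsd <- matrix(-0.5, 6, 6); diag(npsd) <- 1          # equicorrelation -0.5
  expect_error(one_state_spec(100, npsd), "s1.*positive semi-definite")
  expect_error(one_state_spec(100, diag(6) * 2), "unit diagonal")
  expect_error(one_state_spec(5, diag(6)), "duration")
  expect_error(generator_spec(list(), seed = 1), "at least one state")
  expect_error(one_state_spec(100, diag(6), baseline_weights = rep(0.2, 6)),
               "sum to 1")
  expect_error(one_state_spec(100, diag(6), sample_rate_hz = 40), "49")
})

test_that("modulators carry the prescribed zero-lag correlation", {
  tol0 <- 3 * sqrt(envelope_tau(10) / 10000)   # 3 sampling sd at T = 1e4
  m_id <- make_modulators(one_state_spec(10000, diag(6), seed = 11))
  emp <- cor(t(m_id$values))
  expect_lt(max(abs(emp[upper.tri(emp)])), max(0.05, tol0))

  m_neg <- make_modulators(one_state_spec(10000, pair_R(1, 6, -0.9), seed = 12))
  r <- cor(m_neg$values[1, ], m_neg$values[6, ])
  expect_gt(r, -0.95)
  expect_lt(r, -0.8)

  # same-kernel smoothing preserves the full target matrix within sampling error
  R <- target_correlation(-0.6, 0.6, 0.3, 0.2)
  m <- make_modulators(one_state_spec(10000, R, seed = 13))
  emp <- cor(t(m$values))
  expect_lt(max(abs((emp - R)[upper.tri(R)])), 3.5 * sqrt(envelope_tau(10) / 10000))
})

test_that("modulators are deterministic given the seed", {
  s <- one_state_spec(500, pair_R(2, 5, 0.5), seed = 99)
  expect_identical(make_modulators(s)$values, make_modulators(s)$values)
})

test_that("softmax band weights behave as specified", {
  spec <- one_state_spec(50, diag(6), seed = 1, modulation_depth = 0)
  m <- make_modulators(spec)
  w0 <- modulators_to_band_weights(m)
  expect_equal(max(abs(w0$values - spec$baseline_weights)), 0)

  # closed-form softmax: uniform baseline, m = e1, depth 1 -> e/(e+5)
  m$values[] <- 0; m$values[1, ] <- 1
  w1 <- modulators_to_band_weights(m, baseline_weights = rep(1 / 6, 6),
                                   modulation_depth = 1)
  expect_equal(unname(w1$values[1, 1]), exp(1) / (exp(1) + 5),
               tolerance = 1e-12)

  # normalization and monotonicity on random inputs
  m2 <- make_modulators(one_state_spec(300, diag(6), seed = 2))
  w2 <- modulators_to_band_weights(m2)
  expect_lt(max(abs(colSums(w2$values) - 1)), 1e-12)
  expect_true(all(w2$values > 0 & w2$values < 1))
  m3 <- m2; m3$values[4, ] <- m3$values[4, ] + 0.5
  w3 <- modulators_to_band_weights(m3)
  expect_true(all(w3$values[4, ] > w2$values[4, ]))

  m2$values[1, 5] <- NaN
  expect_error(modulators_to_band_weights(m2), "non-finite")
})

test_that("synthesized EEG reproduces the imposed band weights", {
  spec <- one_state_spec(120, diag(6), seed = 3, noise_floor = 0)
  w <- band_weight_series(spec)
  w$values[] <- 0; w$values[3, ] <- 1                  # all alpha
  rec <- synthesize_eeg(w, spec)
  rel <- to_relative(band_power_series(rec))
  expect_gt(mean(rel$values[3, ]), 0.9)

  w$values[] <- 0
  expect_error(synthesize_eeg(w, spec), "zero")
  w$values[3, ] <- 1; w$values[1, 1] <- -0.1
  expect_error(synthesize_eeg(w, spec), "negative")

  r1 <- synthesize_eeg(band_weight_series(spec), spec)
  r2 <- synthesize_eeg(band_weight_series(spec), spec)
  expect_identical(r1$samples, r2$samples)
})

test_that("protocol recordings keep contiguous annotations", {
  ps <- sana_preset("exercise_like", seed = 5)
  w <- band_weight_series(ps)
  ann <- w$annotations
  expect_equal(nrow(ann), 5)
  expect_equal(ann$end_s[5], 4260)
  expect_equal(ann$start_s[-1], ann$end_s[-5])

  short <- generator_spec(
    list(list(label = "a", duration_s = 40, target_R = diag(6)),
         list(label = "b", duration_s = 40, target_R = diag(6))),
    sample_rate_hz = 64, seed = 6)
  out <- make_protocol_recording(short, channel_labels = c("C3", "C4"))
  expect_s3_class(out$recording, "eeg_recording")
  expect_equal(ncol(out$recording$samples), 80 * 64)
  expect_equal(out$annotations$label, c("a", "b"))
})

test_that("preset targets preserve the designed sign pattern after projection", {
  ps <- sana_preset("exercise_like", seed = 1)
  for (s in ps$states) {
    R <- s$target_R
    expect_true(all(R[1, 2:6] < 0))                     # delta anti to all
    expect_true(all(R[cbind(c(4, 4, 5), c(5, 6, 6))] > 0))  # sigma/beta/gamma
    expect_true(sana:::is_psd(R))
  }
  expect_lt(ps$states[[1]]$target_R[2, 3], 0)           # theta-alpha at rest
  expect_gt(ps$states[[3]]$target_R[2, 3], 0)           # ... vs exercise
})
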