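# Preprocessing and spectral decomposition.

test_that("high-pass filter rejects DC and passes in-band tones", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- recording(rbind(rep(5, length(t)), sin(2 * pi * 10 * t)), fs,
                   c("A", "B"))
  out <- highpass_filter(rec, 0.1)
  expect_lt(max(abs(out$samples["A", ])), 5e-6)
  rms_in <- sqrt(mean(rec$samples["B", ]^2))
  rms_out <- sqrt(mean(out$samples["B", ]^2))
  expect_lt(abs(rms_out - rms_in) / rms_in, 0.01)
  expect_error(highpass_filter(rec, 0), "cutoff")
  expect_error(highpass_filter(rec, fs), "cutoff")
})

test_that("surface Laplacian subtracts the neighbor average", {
  fs <- 100
  n <- 500
  common <- sin(seq_len(n) / 7)
  rec <- recording(rbind(common, common, common), fs, c("Fp1", "Fp2", "C3"),
                   annotations = NULL)
  adj <- list(Fp1 = c("Fp2", "C3"), Fp2 = c("Fp1", "C3"), C3 = c("Fp1", "Fp2"))
  out <- surface_laplacian(rec, adj)
  expect_equal(max(abs(out$samples)), 0)

  rec2 <- recording(rbind(rep(1, n), rep(2, n), rep(4, n)), fs,
                    c("A", "B", "C"))
  adj2 <- list(A = c("B", "C"), B = c("A"), C = c("A"))
  out2 <- surface_laplacian(rec2, adj2)
  expect_equal(unique(out2$samples["A", ]), 1 - 3)     # hand arithmetic

  sig <- rnorm(n)
  rec3 <- recording(rbind(sig, rep(0, n), rep(0, n)), fs, c("A", "B", "C"))
  out3 <- surface_laplacian(rec3, adj2)
  expect_equal(out3$samples["A", ], sig)

  expect_error(surface_laplacian(rec2, list(A = "B", B = "A", C = character(0))),
               "'C'")
})

test_that("band power isolates an on-bin tone and matches a flat spectrum", {
  fs <- 100
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  rec <- recording(matrix(sin(2 * pi * 10 * t), 1), fs, "X")
  bp <- band_power_series(rec)
  tot <- colSums(bp$values)
  expect_gt(min(bp$values[3, ] / tot), 0.999)          # alpha owns the tone

  set.seed(42)
  recw <- recording(matrix(rnorm(fs * 600), 1), fs, "X")
  rel <- to_relative(band_power_series(recw))
  expect_lt(max(abs(rowMeans(rel$values) - c(7, 8, 8, 8, 8, 10) / 49)), 0.02)

  expect_error(band_power_series(recording(matrix(rnorm(400), 1), 40, "X")),
               "Nyquist")
  expect_error(band_power_series(recording(matrix(rnorm(50), 1), 100, "X")),
               "window longer")
})

test_that("six-band power of an in-band signal obeys Parseval within 5%", {
  fs <- 128
  n <- fs * 200
  set.seed(7)
  x <- sana:::fft_bandpass(rnorm(n), fs, 0.5, 24.5)
  # restrict to the band union (gaps excluded) so the 6-band sum is the total
  bands <- band_definitions()
  y <- 0
  for (i in 1:6) y <- y + sana:::fft_bandpass(x, fs, bands$f_lo[i], bands$f_hi[i])
  rec <- recording(matrix(y, 1), fs, "X")
  bp <- band_power_series(rec)
  expect_lt(abs(mean(colSums(bp$values)) - var(y)) / var(y), 0.05)
})

test_that("relative normalization projects onto the simplex and flags zeros", {
  vals <- cbind(c(2, 1, 1, 0, 0, 0), rep(0, 6), runif(6))
  bp <- band_power(vals, mode = "absolute", time_s = 0:2, channel = "X")
  expect_warning(rel <- to_relative(bp), "1 zero-total")
  expect_equal(rel$values[, 1], c(0.5, 0.25, 0.25, 0, 0, 0),
               ignore_attr = TRUE)
  expect_true(all(is.nan(rel$values[, 2])))
  expect_true(rel$flagged[2])
  expect_lt(max(abs(colSums(rel$values[, c(1, 3)]) - 1)), 1e-12)
  expect_error(to_relative(rel), "absolute-mode")
})

test_that("moving-average smoothing preserves length, mass and linearity", {
  set.seed(1)
  vals <- matrix(rexp(6 * 1800), 6)
  vals <- sweep(vals, 2, colSums(vals), "/")
  bp <- band_power(vals, mode = "relative", time_s = 0:1799, channel = "X")
  sm <- smooth_band_power(bp, 14)
  expect_equal(ncol(sm$values), 1800)
  expect_lt(max(abs(colSums(sm$values) - 1)), 1e-9)

  const <- band_power(matrix(rep(c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1), 100), 6),
                      mode = "relative", time_s = 0:99, channel = "X")
  smc <- smooth_band_power(const, 14)
  expect_equal(smc$values, const$values, tolerance = 1e-12)

  # impulse response: plateau of 1/14 over the centered 14-sample support
  x <- numeric(300); x[100] <- 1
  ma <- sana:::moving_average(x, 14)
  expect_equal(sum(ma > 1 / 14 - 1e-12), 14)
  expect_equal(max(ma), 1 / 14)
  # linearity: smoothing commutes with summing bands
  expect_equal(colSums(sm$values),
               sana:::moving_average(colSums(bp$values), 14),
               tolerance = 1e-12)

  expect_error(smooth_band_power(const, 200), "longer")
})
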