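# Profiles, degree of coupling, classification and the threshold sweep.

test_that("pooling concatenates valid values across subjects and tests", {
  spec <- one_state_spec(90, diag(6), seed = 1)        # 3 windows each
  cw1 <- coupling_windows(smoothed_series(spec, "S01"))
  cw2 <- coupling_windows(smoothed_series(one_state_spec(90, diag(6), seed = 2),
                                          "S02"))
  both <- sana:::bind_coupling_windows(list(cw1, cw2))
  expect_length(pool_values(both, "delta-theta", state = "s1"), 6)
  expect_length(pool_values(both, "delta-theta", subjects = "S01"), 3)
  expect_identical(pool_values(both, "delta-theta", subjects = "S02"),
                   pool_values(cw2, c(1, 2)))
  expect_error(pool_values(both, "delta-theta", state = "nope"), "nope")
})

test_that("profiles histogram with the stated bin conventions", {
  cfg <- analysis_config()
  p <- build_profile(rep(0.51, 20), cfg)
  expect_equal(sum(p$raw_counts), 20)
  expect_equal(sum(p$raw_counts > 0), 1)               # single peak bin
  expect_equal(which(p$raw_counts > 0), 31)            # [0.50, 0.55)
  expect_lte(sum(p$profile > 0), 5)                    # smoothing support
  expect_equal(sum(p$profile), 1, tolerance = 1e-12)   # mass conserved

  # exactly uniform counts: profile identically 1, unchanged by smoothing
  u <- build_profile(rep(seq(-0.975, 0.975, by = 0.05), each = 3), cfg)
  expect_equal(u$profile, rep(1, 40), tolerance = 1e-12)

  # +1 goes to the last bin, -1 to the first
  b <- build_profile(c(-1, 1), cfg)
  expect_equal(b$raw_counts[c(1, 40)], c(1, 1))
  expect_error(build_profile(c(0.2, 1.2), cfg), "outside")
})

test_that("degree of coupling counts strict threshold exceedances", {
  expect_equal(degree_of_coupling(c(0.6, 0.7, -0.8, 0.2, 0.0)),
               c(D_plus = 0.4, D_minus = 0.2))
  expect_equal(degree_of_coupling(rep(0.5, 10)), c(D_plus = 0, D_minus = 0))
  expect_error(degree_of_coupling(numeric(0)), "empty")
  expect_error(degree_of_coupling(0.2, threshold = 0), "threshold")

  # tail fractions are non-increasing in the threshold
  set.seed(5)
  v <- tanh(rnorm(500))
  d <- sapply(c(0.3, 0.4, 0.5, 0.6, 0.7),
              function(th) degree_of_coupling(v, th))
  expect_true(all(diff(d["D_plus", ]) <= 0))
  expect_true(all(diff(d["D_minus", ]) <= 0))
})

test_that("raw-count and area-under-profile estimators agree at scale", {
  set.seed(9)
  v <- tanh(rnorm(5000, mean = 0.3, sd = 0.6))
  prof <- build_profile(v, analysis_config())
  raw <- degree_of_coupling(v)
  area <- degree_of_coupling_area(prof)
  expect_lt(max(abs(raw - area)), 0.02)
})

test_that("pairs classify by strict per-state dominance", {
  rest <- fake_degree(0.1, 0.3, "rest")
  ex <- fake_degree(0.2, 0.6, "exercise")
  cls <- classify_pairs(list(rest, ex))
  expect_true(all(cls$class == "anti"))
  cls2 <- classify_pairs(list(fake_degree(0.4, 0.1, "rest"),
                              fake_degree(0.7, 0.2, "exercise")))
  expect_true(all(cls2$class == "positive"))
  # dominance switching across states, and exact ties, are both mixed
  cls3 <- classify_pairs(list(fake_degree(0.4, 0.1, "rest"),
                              fake_degree(0.1, 0.4, "exercise")))
  expect_true(all(cls3$class == "mixed"))
  cls4 <- classify_pairs(list(fake_degree(0.2, 0.2, "rest"),
                              fake_degree(0.3, 0.3, "exercise")))
  expect_true(all(cls4$class == "mixed"))
  expect_error(classify_pairs(list(rest)), "two states")
})

test_that("threshold sweep reports monotone tails on null data", {
  # i.i.d. relative samples: genuinely null windows (no envelope memory)
  set.seed(21)
  mk_null <- function(state, len) {
    v <- matrix(rexp(6 * len), 6)
    band_power(sweep(v, 2, colSums(v), "/"), mode = "smoothed_relative",
               time_s = seq_len(len) - 1, channel = "X",
               annotations = session_annotations(state, 0, len))
  }
  cw <- sana:::bind_coupling_windows(
    list(coupling_windows(mk_null("a", 600)),
         coupling_windows(mk_null("b", 600))))
  sw <- threshold_sweep(cw)
  tab <- sw$table
  for (pr in unique(tab$pair)) {
    sub <- tab[tab$pair == pr & tab$state == "a", ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$D_plus) <= 0))
    expect_true(all(diff(sub$D_minus) <= 0))
    expect_true(all(sub$D_plus[sub$threshold == 0.3] <= 0.5))
    expect_true(all(sub$D_minus[sub$threshold == 0.3] <= 0.5))
  }
  expect_error(threshold_sweep(cw, thresholds = c(0, 0.5)), "thresholds")
})
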