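test_that("filterbank centers are geometric with the documented endpoints", {
  fb <- design_filterbank(40, 4.07, 193.2)
  expect_identical(nrow(fb), 40L)
  expect_true(all(diff(fb$center) > 0))
  ratios <- fb$center[-1] / fb$center[-40]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(fb$center[1], 4.07)
  expect_equal(fb$center[40], 193.2)
  expect_true(all(fb$bw_sd > 0))

  fb2 <- design_filterbank(2, 10, 40)
  expect_equal(fb2$center, c(10, 40))
})

test_that("the high-gamma band contains the analytically expected filter count", {
  fb <- design_filterbank(40, 4.07, 193.2)
  # oracle: closed-form index arithmetic on the geometric progression
  r <- (193.2 / 4.07)^(1 / 39)
  k_lo <- ceiling(log(70 / 4.07) / log(r)) + 1
  k_hi <- floor(log(150 / 4.07) / log(r)) + 1
  expected <- as.integer(k_hi - k_lo + 1)
  expect_identical(sum(fb$center >= 70 & fb$center <= 150), expected)
  expect_identical(expected, 8L)
})

test_that("canonical bands are disjoint and cover each filter at most once", {
  cb <- canonical_bands()
  fb <- design_filterbank()
  for (i in seq_len(nrow(cb) - 1)) expect_lt(cb$f_hi[i], cb$f_lo[i + 1])
  hits <- vapply(fb$center, function(cf) {
    sum(cf >= cb$f_lo & cf <= cb$f_hi)
  }, numeric(1))
  expect_true(all(hits[fb$center >= 4 & fb$center <= 150] <= 1))
})

test_that("analytic amplitude recovers tone and AM envelopes", {
  fs <- 400
  t <- seq(0, 5, by = 1 / fs)
  inner <- 200:1800  # away from edges
  tone <- cos(2 * pi * 110 * t)
  a <- analytic_amplitude(tone, fs, 110, 110 / 7)
  expect_true(all(abs(a[inner] - 1) < 0.05))

  expect_identical(analytic_amplitude(rep(0, 512), fs, 110, 10), rep(0, 512))

  env <- 1 + 0.5 * cos(2 * pi * 2 * t)
  a2 <- analytic_amplitude(env * cos(2 * pi * 110 * t), fs, 110, 110 / 7)
  expect_gt(stats::cor(a2[inner], env[inner]), 0.99)

  expect_error(analytic_amplitude(tone, fs, 250, 10), "Nyquist")
})

test_that("common-average referencing removes the common mode only", {
  s <- sin(seq(0, 10, length.out = 400))
  pair <- cbind(s, -s)
  expect_equal(preprocess_voltage(pair, 400), pair, tolerance = 1e-12,
               ignore_attr = TRUE)
  same <- cbind(s, s, s)
  expect_true(all(abs(preprocess_voltage(same, 400)) < 1e-12))
  expect_error(preprocess_voltage(pair, 400, bad_channels = 1:2), "bad")
})

test_that("frequency-domain decimation shortens by the rate ratio and keeps content", {
  n <- 1200
  t <- (seq_len(n) - 1) / 1200
  x <- cbind(cos(2 * pi * 50 * t), sin(2 * pi * 30 * t))
  out <- preprocess_voltage(x, 1200, fs_out = 400)
  expect_identical(nrow(out), 400L)
  # a 50 Hz tone survives 400 Hz decimation; compare against the ideal
  t2 <- (seq_len(n / 3) - 1) / 400
  ideal <- cos(2 * pi * 50 * t2) - (cos(2 * pi * 50 * t2) + sin(2 * pi * 30 * t2)) / 2
  expect_gt(stats::cor(out[, 1], ideal), 0.999)
})

test_that("baseline z-scoring matches its definition and degenerates loudly", {
  set.seed(1)
  x <- matrix(abs(stats::rnorm(600)) + 1, 300, 2)
  z <- zscore_baseline(x, fs = 100, baseline = c(0, 2))
  expect_lt(max(abs(colMeans(z[1:200, ]))), 1e-9)
  expect_equal(unname(apply(z[1:200, ], 2, sd)), c(1, 1), tolerance = 1e-9)
  # scale invariance
  expect_equal(zscore_baseline(2 * x, 100, c(0, 2)), z, tolerance = 1e-9)
  expect_error(zscore_baseline(matrix(1, 100, 2), 100, c(0, 0.5)),
               "zero baseline variance")
})

test_that("band aggregation is the unweighted mean of qualifying filters", {
  fb <- design_filterbank(3, 80, 140)  # centers all inside high gamma
  amps <- array(0, dim = c(4, 2, 3))
  amps[1, 1, ] <- c(1, 2, 3)
  agg <- aggregate_to_band(amps, fb, "high_gamma")
  expect_equal(agg[1, 1], 2)
  single <- aggregate_to_band(amps, fb, c(fb$center[2] - 1, fb$center[2] + 1))
  expect_equal(single[1, 1], 2)
  expect_error(aggregate_to_band(amps, fb, "theta"), "no filter")
})

test_that("constant-ratio downsampling realizes the documented rates", {
  x <- matrix(stats::rnorm(400), 200, 2)
  same <- downsample_constant_ratio(x, 200, 112.5)
  expect_identical(same$fs, 200)
  expect_identical(same$values, x)

  d <- downsample_constant_ratio(x, 200, 22.5)
  expect_equal(d$fs, 40)
  expect_identical(nrow(d$values), 40L)

  d2 <- downsample_constant_ratio(x, 200, 5.5)
  target <- 5.5 * 200 / 112.5
  expect_lt(abs(d2$fs - target) / target, 0.01)
  # ratio preservation across all canonical band centers
  for (bc in c(5.5, 11, 22, 44.5, 112.5)) {
    fs_new <- downsample_constant_ratio(x, 200, bc)$fs
    expect_lt(abs(bc / fs_new - 112.5 / 200) / (112.5 / 200), 0.01)
  }
  expect_error(downsample_constant_ratio(x, 200, 150), "upsampling")
})

test_that("trial windows have 258 samples at 200 Hz and 4% edge normalization", {
  expect_identical(window_samples(200), 258L)
  expect_equal(max(1L, floor(0.04 * window_samples(200))), 10)

  amp <- matrix(5, 1000, 3)  # constant trace
  w <- extract_trial_window(amp, 200, event_time = 2.5)
  expect_identical(dim(w), c(258L, 3L))
  expect_true(all(abs(w) < 1e-12))

  # edge-mean subtraction uses exactly the first and last 10 samples
  amp2 <- matrix(0, 1000, 1)
  seg_rows <- round((2.5 - 0.5) * 200) + 1:258
  amp2[seg_rows[1:10], 1] <- 1    # first-edge samples only
  w2 <- extract_trial_window(amp2, 200, 2.5)
  expect_equal(w2[11, 1], -10 / 20)

  expect_error(extract_trial_window(amp, 200, 0.1), "outside")
})

test_that("the feature pipeline is deterministic", {
  set.seed(4)
  v <- matrix(stats::rnorm(2000), 1000, 2)
  fb <- design_filterbank(5, 10, 150)
  a1 <- filter_amplitudes(v, 400, fb)
  a2 <- filter_amplitudes(v, 400, fb)
  expect_identical(a1, a2)
})
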