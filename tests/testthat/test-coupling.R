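test_that("trial averaging collapses trials within class", {
  amp <- array(0, dim = c(4, 2, 3))
  amp[1, , ] <- 1; amp[2, , ] <- 3      # class a: mean 2
  amp[3, , ] <- 5; amp[4, , ] <- -5     # class b: mean 0
  avg <- trial_average(amp, c("a", "a", "b", "b"))
  expect_identical(dim(avg), c(2L, 2L, 3L))
  expect_true(all(avg["a", , ] == 2))
  expect_true(all(avg["b", , ] == 0))
  expect_error(trial_average(amp, c("a", "a", "b", "b"), classes = c("a", "z")),
               "without trials")
})

test_that("band averaging over the frequency axis is an unweighted mean", {
  D <- array(0, dim = c(2, 3, 2, 4))
  D[, 1, , ] <- 1; D[, 2, , ] <- 3; D[, 3, , ] <- 10
  centers <- c(80, 120, 20)
  hg <- band_average(D, centers, "high_gamma")     # filters 1 and 2
  expect_true(all(hg == 2))
  single <- band_average(D, centers, c(15, 29))    # only filter 3
  expect_true(all(single == 10))
  expect_error(band_average(D, centers, c(300, 400)), "no frequency")
})

test_that("correlation spectra are bounded, self-consistent and count exclusions", {
  set.seed(20)
  n_cv <- 3; n_e <- 4; n_t <- 100
  D <- array(stats::rnorm(n_cv * 2 * n_e * n_t), dim = c(n_cv, 2, n_e, n_t))
  D[, 2, , ] <- D[, 1, , ]             # entry 2 duplicates entry 1
  D[1, 1, 1, ] <- 7                    # one zero-variance pair
  ref <- D[, 1, , , drop = FALSE]; dim(ref) <- c(n_cv, n_e, n_t)
  sp <- correlation_spectrum(D, centers = c(100, 110), reference = ref)
  expect_true(all(abs(sp$mean_r) <= 1))
  expect_equal(sp$mean_r[2], sp$mean_r[1])
  expect_identical(sp$n_excluded, c(1L, 1L))
  expect_identical(sp$n_pairs, c(11L, 11L))
  expect_equal(sp$mean_r[1], 1)        # self-correlation
  expect_error(correlation_spectrum(D[, , , 1:2, drop = FALSE], c(1, 2), ref),
               "3 time samples")
})

test_that("peri-transition power windows average the documented samples", {
  t_axis <- (0:257) / 200 - 0.5
  expect_identical(sum(t_axis >= -0.070 - 1e-9 & t_axis < 0.140 - 1e-9), 42L)

  ref <- array(3, dim = c(2, 3, 258))
  A <- hg_power_window(ref, t_axis)
  expect_identical(dim(A), c(3L, 2L))   # electrode x class
  expect_true(all(A == 3))

  # a positive bump centered at the transition beats the trace's edge mean
  bump <- exp(-0.5 * (t_axis / 0.05)^2)
  ref2 <- array(rep(bump, each = 2 * 1), dim = c(2, 1, 258))
  A2 <- hg_power_window(ref2, t_axis)
  edge_mean <- mean(bump[c(1:10, 249:258)])
  expect_gt(A2[1, 1], edge_mean)
  expect_error(hg_power_window(ref, t_axis, window = c(5, 6)), "outside")
})

test_that("the activity-threshold fit inverts exact linear structure", {
  A <- matrix(seq(0.1, 4, length.out = 40), 8, 5)
  C <- 0.5 * A - 1
  sp <- fit_activity_threshold(C, A)
  expect_equal(sp$slope, 0.5, tolerance = 1e-9)
  expect_equal(sp$intercept, -1, tolerance = 1e-9)
  expect_equal(sp$threshold, 2, tolerance = 1e-9)
  expect_identical(sp$active, A > 2)
  expect_false(sp$degenerate)

  flat <- fit_activity_threshold(matrix(0.3, 8, 5), A)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$threshold))
  expect_error(fit_activity_threshold(c(0.1, 0.2), c(-1, -2)), "positive")
})

test_that("graded planted coupling recovers the activity threshold within 20%", {
  cfg <- sim_config(n_electrodes = 12, trials_per_cv = c(25, 25),
                    coupling_mode = "graded", activity_threshold = 1,
                    seed = 7, cv_subset = make_inventory()$cvs)
  ds <- simulate_amplitude_dataset(cfg)
  m <- coupling_measurements(ds)
  expect_gte(length(m$A), 500)
  sp <- fit_activity_threshold(m$C, m$A)
  expect_lt(abs(sp$threshold - 1) / 1, 0.2)
})

test_that("grouped spectra separate planted active and inactive couplings", {
  cfg <- sim_config(n_electrodes = 10, trials_per_cv = c(25, 25),
                    coupling_beta_hg = 0.6, coupling_inactive = 0,
                    seed = 13, cv_subset = make_inventory()$cvs[1:30])
  ds <- simulate_amplitude_dataset(cfg)
  m <- coupling_measurements(ds)
  # split at the generator's truth: the test isolates the grouped spectra,
  # not the threshold fit (tested separately)
  split <- structure(list(slope = 1, intercept = 0, threshold = 0.5,
                          active = m$active, n_fit = length(m$A),
                          degenerate = FALSE), class = "activity_split")
  gs <- grouped_correlation_spectra(m$ta$D, m$centers, m$ref, split,
                                    C = m$C, A = m$A)
  beta_row <- which(gs$active$center == 22)
  expect_gt(gs$active$mean_r[beta_row], 0.35)
  expect_lt(abs(gs$inactive$mean_r[beta_row]), 0.15)
  expect_identical(sum(gs$bins$count), sum(is.finite(m$C) & is.finite(m$A)))
  expect_identical(nrow(gs$bins), 9L)
})

test_that("aggregation masks opposite-signed couplings that disaggregation reveals", {
  cfg <- sim_config(n_electrodes = 12, trials_per_cv = c(25, 25),
                    coupling_beta_hg = 0.6, coupling_inactive = -0.3,
                    seed = 17, cv_subset = make_inventory()$cvs[1:30])
  ds <- simulate_amplitude_dataset(cfg)
  m <- coupling_measurements(ds)
  act_mean <- mean(m$C[m$active])
  inact_mean <- mean(m$C[!m$active])
  pooled <- mean(m$C)
  expect_gt(act_mean, 0.4)
  expect_lt(inact_mean, -0.15)
  expect_gt(pooled, inact_mean)
  expect_lt(pooled, act_mean)
})

test_that("reference-band self-similarity beats beta when no coupling is planted", {
  cfg <- sim_config(n_electrodes = 8, trials_per_cv = c(15, 15),
                    coupling_beta_hg = 0, seed = 23,
                    bands = c("beta", "gamma", "high_gamma"),
                    cv_subset = make_inventory()$cvs[1:12])
  ds <- simulate_amplitude_dataset(cfg)
  ta <- trial_average_tensor(ds)
  centers <- c(beta = 22, gamma = 44.5, high_gamma = 110)[ta$frequency]
  ref <- band_average(ta$D, centers, "high_gamma")
  sp <- correlation_spectrum(ta$D, centers, ref)
  r_hg <- sp$mean_r[sp$center == 110]
  r_beta <- sp$mean_r[sp$center == 22]
  expect_gt(r_hg, r_beta)
  expect_gt(r_hg, 0.9)
})
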