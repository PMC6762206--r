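#' Configuration for the synthetic ECoG generator
#'
#' Bundles and validates the parameters of the synthetic dataset generators.
#' Defaults reproduce the recording conditions the analyses assume: 86
#' ventral sensorimotor electrodes, 10 to 105 repetitions per consonant-vowel
#' syllable, voltage sampled at 400 Hz, amplitudes at 200 Hz, and a trial
#' window from 0.5 s before to 0.79 s after the consonant-to-vowel acoustic
#' transition (258 amplitude samples).
#'
#' @param n_electrodes Number of electrodes.
#' @param trials_per_cv Length-2 integer range `(low, high)`; each syllable's
#'   trial count is drawn uniformly from it. `low` must be at least 10, the
#'   minimum class size retained by the cross-validation splitter.
#' @param fs_voltage Voltage sampling rate, Hz.
#' @param fs_amplitude Amplitude sampling rate, Hz.
#' @param window `(pre_s, post_s)` trial window around the transition, s.
#' @param coupling_beta_hg Planted Pearson correlation between the beta and
#'   high-gamma envelopes at engaged (electrode, syllable) pairs, in
#'   `[-1, 1]`.
#' @param coupling_inactive Planted correlation at non-engaged pairs
#'   (default 0).
#' @param coupling_mode `"two_group"` plants `coupling_beta_hg` at engaged
#'   pairs and `coupling_inactive` elsewhere; `"graded"` plants a correlation
#'   linear in the pair's expected high-gamma activity,
#'   `coupling_slope * (activity - activity_threshold)` (clamped to
#'   `[-0.95, 0.95]`), so the correlation crosses zero exactly at
#'   `activity_threshold`.
#' @param coupling_slope Slope of the graded coupling law, per z-unit of
#'   activity.
#' @param activity_threshold Activity (z-units) at which graded coupling
#'   crosses zero.
#' @param active_level Mean z-scored high-gamma amplitude at fully engaged
#'   pairs.
#' @param inactive_level Mean z-scored high-gamma amplitude at non-engaged
#'   pairs (slightly below baseline, as movement-unrelated cortex tends to
#'   be).
#' @param beta_level Mean z-scored beta amplitude (below baseline: beta
#'   desynchronizes during movement).
#' @param separation Scale of the syllable-specific spatial pattern on top of
#'   articulator engagement; the dial controlling class separability.
#' @param fluct_sd Standard deviation of the trial-shared envelope
#'   fluctuations (the component carrying the planted coupling).
#' @param noise_sd Standard deviation of per-trial additive noise.
#' @param lognormal_sigma Log-scale sigma of the log-normal envelope
#'   fluctuations.
#' @param smooth_ms Gaussian smoothing scale of the envelope fluctuations,
#'   ms.
#' @param bump_scale Amplitude of a deterministic peri-transition high-gamma
#'   bump at engaged pairs (0 disables it; used for time-resolved decoding
#'   demonstrations).
#' @param baseline_s Length of the quiescent baseline segment prepended to
#'   voltage recordings, s.
#' @param bands Character vector of canonical bands to synthesize.
#' @param cv_subset Optional character vector restricting the syllables
#'   generated (defaults to the full inventory).
#' @param seed Integer seed; identical configurations and seeds give
#'   identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_electrodes = 86,
                       trials_per_cv = c(10, 105),
                       fs_voltage = 400,
                       fs_amplitude = 200,
                       window = c(0.5, 0.79),
                       coupling_beta_hg = 0,
                       coupling_inactive = 0,
                       coupling_mode = c("two_group", "graded"),
                       coupling_slope = 0.25,
                       activity_threshold = 1,
                       active_level = 2,
                       inactive_level = -0.3,
                       beta_level = -0.3,
                       separation = 1,
                       fluct_sd = 1,
                       noise_sd = 1,
                       lognormal_sigma = 0.5,
                       smooth_ms = 50,
                       bump_scale = 0,
                       baseline_s = 10,
                       bands = c("beta", "high_gamma"),
                       cv_subset = NULL,
                       seed = 1) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(length(trials_per_cv) == 2, length(window) == 2)
  if (sum(window) <= 0) stop("degenerate window: pre_s + post_s must be > 0")
  if (trials_per_cv[1] < 10) {
    stop("trials_per_cv low must be >= 10 (smaller classes are excluded downstream)")
  }
  if (trials_per_cv[2] < trials_per_cv[1]) stop("trials_per_cv must be (low, high)")
  if (abs(coupling_beta_hg) > 1 || abs(coupling_inactive) > 1) {
    stop("coupling must lie in [-1, 1]")
  }
  if (!"high_gamma" %in% bands) bands <- c(bands, "high_gamma")
  structure(list(
    n_electrodes = n_electrodes, trials_per_cv = as.integer(trials_per_cv),
    fs_voltage = fs_voltage, fs_amplitude = fs_amplitude, window = window,
    coupling_beta_hg = coupling_beta_hg,
    coupling_inactive = coupling_inactive, coupling_mode = coupling_mode,
    coupling_slope = coupling_slope, activity_threshold = activity_threshold,
    active_level = active_level, inactive_level = inactive_level,
    beta_level = beta_level, separation = separation, fluct_sd = fluct_sd,
    noise_sd = noise_sd, lognormal_sigma = lognormal_sigma,
    smooth_ms = smooth_ms, bump_scale = bump_scale, baseline_s = baseline_s,
    bands = bands, cv_subset = cv_subset, seed = as.integer(seed)
  ), class = "sim_config")
}

# Smoothed standard-normal latent series: white noise mixed across columns
# (for cross-band correlation) must be smoothed with the SAME kernel so the
# zero-lag correlation of the smoothed series equals that of the white noise.
smooth_standardize <- function(w, sd_samples) {
  if (sd_samples <= 0) return(w)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  sm <- stats::filter(w, k, sides = 2, circular = TRUE)
  as.matrix(sm) / sqrt(sum(k^2))
}

# Invert the log-normal attenuation so the planted Pearson correlation of
# the envelope fluctuations equals `rho` exactly:
# corr(exp(s z1), exp(s z2)) = (exp(s^2 rho_l) - 1) / (exp(s^2) - 1).
latent_rho <- function(rho, s) {
  x <- 1 + rho * (expm1(s^2))
  if (x <= 0) stop("coupling ", rho, " not attainable with lognormal_sigma ", s)
  log(x) / s^2
}

# Zero-mean unit-sd lognormal transform of a standard normal series.
lognormal_fluct <- function(z, s) {
  (exp(s * z) - exp(s^2 / 2)) / sqrt(expm1(s^2) * exp(s^2))
}

# Uniform integer trial counts on [low, high]; robust to low == high (a bare
# scalar passed to sample() would be read as 1:n).
draw_counts <- function(rng, n) {
  rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
}

# Expected (trial-shared) per-pair structure: engagement, class means,
# planted per-pair correlations and the active mask. Shared by both
# generators.
plan_structure <- function(config, inventory, amap) {
  cvs <- config$cv_subset %||% inventory$cvs
  stopifnot(all(cvs %in% inventory$cvs))
  art <- inventory$articulator[cvs]
  art_idx <- match(art, colnames(amap))
  if (anyNA(art_idx)) {
    # maps with fewer articulators than the inventory fold extras onto the
    # last column
    art_idx[is.na(art_idx)] <- ncol(amap)
  }
  engagement <- amap[, art_idx, drop = FALSE]   # electrode x CV
  colnames(engagement) <- cvs
  modulation <- matrix(stats::rnorm(length(engagement)),
                       nrow(engagement), ncol(engagement),
                       dimnames = dimnames(engagement))
  class_means <- config$inactive_level +
    engagement * (config$active_level - config$inactive_level) +
    config$separation * engagement * 0.5 * modulation
  active <- engagement > 0.5
  rho <- switch(config$coupling_mode,
    two_group = ifelse(active, config$coupling_beta_hg,
                       config$coupling_inactive),
    graded = pmin(0.95, pmax(-0.95,
      config$coupling_slope * (class_means - config$activity_threshold)))
  )
  list(cvs = cvs, engagement = engagement, modulation = modulation,
       class_means = class_means, active = active, rho = rho)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a labeled multi-band amplitude dataset
#'
#' Generates z-scored analytic-amplitude tensors (trial x electrode x time)
#' for the requested canonical bands, with the statistical structure the
#' downstream analyses assume:
#'
#' * syllable classes are separable in proportion to articulator engagement
#'   (`separation` dial), with ragged per-class trial counts;
#' * at each (electrode, syllable) pair the beta and high-gamma envelope
#'   fluctuations are drawn through a Gaussian copula with log-normal
#'   margins, calibrated so the planted Pearson correlation equals the
#'   configured coupling (`two_group` or `graded` law);
#' * the fluctuations are shared across trials of a syllable (they survive
#'   trial averaging) while per-trial noise does not.
#'
#' @param config A [sim_config()].
#' @param inventory A [make_inventory()] (built if missing).
#' @param amap An [make_articulator_map()] engagement matrix (built from the
#'   config if missing).
#' @return A `cv_dataset`: list with `amplitudes` (named list of
#'   `[trial x electrode x time]` arrays, all at `fs_amplitude`), `labels`,
#'   `t` (time axis, s, 0 = transition), `fs`, `window`, `event_index`, and
#'   `truth` (generating parameters: class means, planted correlations,
#'   active mask, engagement, modulation, config) sufficient to recompute
#'   expected class separations and couplings.
#' @export
simulate_amplitude_dataset <- function(config = sim_config(),
                                       inventory = make_inventory(),
                                       amap = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(amap)) {
    amap <- make_articulator_map(config$n_electrodes,
                                 min(4L, config$n_electrodes),
                                 seed = config$seed + 1L)
  }
  stopifnot(nrow(amap) == config$n_electrodes)

  fs <- config$fs_amplitude
  n_t <- round(fs * sum(config$window))
  t_axis <- (seq_len(n_t) - 1) / fs - config$window[1]
  sd_samples <- config$smooth_ms / 1000 * fs
  s <- config$lognormal_sigma

  set.seed(config$seed + 2L)
  str <- plan_structure(config, inventory, amap)
  cvs <- str$cvs
  n_cv <- length(cvs)
  n_e <- config$n_electrodes
  n_pairs <- n_e * n_cv

  counts <- draw_counts(config$trials_per_cv, n_cv)
  labels <- rep(cvs, times = counts)
  n_trials <- length(labels)

  # trial-shared high-gamma fluctuations per (electrode, CV) pair
  w_hg <- matrix(stats::rnorm(n_t * n_pairs), n_t, n_pairs)
  z_hg <- smooth_standardize(w_hg, sd_samples)
  f_hg <- lognormal_fluct(z_hg, s)      # n_t x (electrode*CV), unit sd

  bump <- exp(-0.5 * (t_axis / 0.12)^2)

  # shared (trial-averaged) high-gamma envelope per pair, time x pair
  mean_hg <- matrix(rep(as.vector(str$class_means), each = n_t), n_t) +
    config$bump_scale * outer(bump, as.vector(str$engagement)) +
    config$fluct_sd * f_hg

  # Planted beta coupling. In graded mode the law is applied to the pair's
  # REALIZED peri-transition amplitude (the quantity the downstream analysis
  # thresholds), so the planted zero-crossing is recoverable without
  # errors-in-variables bias from the envelope fluctuations.
  if (config$coupling_mode == "graded") {
    win <- t_axis >= -0.070 - 1e-9 & t_axis < 0.140 - 1e-9
    realized <- colMeans(mean_hg[win, , drop = FALSE])
    rho_vec <- pmin(0.95, pmax(-0.95,
      config$coupling_slope * (realized - config$activity_threshold)))
    str$rho <- matrix(rho_vec, n_e, n_cv, dimnames = dimnames(str$rho))
    str$activity_realized <- matrix(realized, n_e, n_cv,
                                    dimnames = dimnames(str$rho))
  }
  rho_l <- vapply(str$rho, latent_rho, numeric(1), s = s)
  w_ind <- matrix(stats::rnorm(n_t * n_pairs), n_t, n_pairs)
  w_beta <- sweep(w_hg, 2, rho_l, `*`) +
    sweep(w_ind, 2, sqrt(1 - rho_l^2), `*`)
  z_beta <- smooth_standardize(w_beta, sd_samples)
  f_beta <- lognormal_fluct(z_beta, s)
  mean_beta <- config$beta_level + config$fluct_sd * f_beta

  shared <- list(high_gamma = mean_hg, beta = mean_beta)
  extra <- setdiff(config$bands, names(shared))
  for (b in extra) {
    zb <- smooth_standardize(matrix(stats::rnorm(n_t * n_pairs), n_t, n_pairs),
                             sd_samples)
    shared[[b]] <- config$fluct_sd * lognormal_fluct(zb, s)
  }
  shared <- shared[intersect(c("theta", "alpha", "beta", "gamma",
                               "high_gamma"), config$bands)]

  cv_idx <- match(labels, cvs)
  amplitudes <- lapply(shared, function(m) {
    arr <- array(0, dim = c(n_trials, n_e, n_t))
    for (r in seq_len(n_trials)) {
      cols <- (cv_idx[r] - 1L) * n_e + seq_len(n_e)
      arr[r, , ] <- t(m[, cols, drop = FALSE]) +
        matrix(stats::rnorm(n_e * n_t, sd = config$noise_sd), n_e, n_t)
    }
    arr
  })

  structure(list(
    amplitudes = amplitudes, labels = labels, t = t_axis, fs = fs,
    window = config$window,
    event_index = round(config$window[1] * fs),
    truth = list(cvs = cvs, class_means = str$class_means, rho = str$rho,
                 active = str$active, engagement = str$engagement,
                 modulation = str$modulation,
                 activity_realized = str$activity_realized,
                 amap = amap, config = config)
  ), class = "cv_dataset")
}

# Canonical carrier frequency used for each band's oscillation in the
# voltage generator (band midpoints).
band_carriers <- c(theta = 5.5, alpha = 11, beta = 22, gamma = 44.5,
                   high_gamma = 110)

#' Simulate a continuous multi-electrode voltage recording
#'
#' Builds raw voltage as a sum of band-limited oscillations whose envelopes
#' follow the same articulator-structured, coupling-planted law as
#' [simulate_amplitude_dataset()], plus 1/f background noise. A quiescent
#' baseline segment is prepended for z-scoring. Passing the output through
#' the spectral pipeline recovers the planted envelope structure.
#'
#' @inheritParams simulate_amplitude_dataset
#' @param envelope_base Baseline (quiescent) envelope amplitude per band, in
#'   voltage units.
#' @param pink_sd Standard deviation of the 1/f background.
#' @return A `cv_voltage`: list with `voltage` (`[time x electrode]` at
#'   `fs_voltage`), `fs`, `event_times` (s, one per trial, at the
#'   consonant-vowel transition), `labels`, `baseline` (`c(start, end)` s of
#'   the quiescent segment), and `truth` (including the planted per-band
#'   envelopes).
#' @export
simulate_voltage_dataset <- function(config = sim_config(),
                                     inventory = make_inventory(),
                                     amap = NULL,
                                     envelope_base = c(theta = 4, alpha = 3,
                                                       beta = 2.5, gamma = 1.5,
                                                       high_gamma = 1),
                                     pink_sd = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(amap)) {
    amap <- make_articulator_map(config$n_electrodes,
                                 min(4L, config$n_electrodes),
                                 seed = config$seed + 1L)
  }
  fs <- config$fs_voltage
  set.seed(config$seed + 2L)
  str <- plan_structure(config, inventory, amap)
  cvs <- str$cvs
  counts <- draw_counts(config$trials_per_cv, length(cvs))
  labels <- rep(cvs, times = counts)
  n_trials <- length(labels)
  n_e <- config$n_electrodes

  trial_len <- sum(config$window)
  n_trial_t <- round(fs * trial_len)
  n_base <- round(fs * config$baseline_s)
  n_total <- n_base + n_trials * n_trial_t
  t_total <- (seq_len(n_total) - 1) / fs
  event_times <- config$baseline_s +
    (seq_len(n_trials) - 1) * trial_len + config$window[1]

  sd_samples <- config$smooth_ms / 1000 * fs
  s <- config$lognormal_sigma
  bands <- names(band_carriers)[names(band_carriers) %in% config$bands]
  cv_idx <- match(labels, cvs)

  # per-trial activity drive (log-envelope units) for high gamma
  drive <- matrix(0, n_total, n_e)
  gate <- rep(1, n_trial_t)
  for (r in seq_len(n_trials)) {
    rows <- n_base + (r - 1L) * n_trial_t + seq_len(n_trial_t)
    drive[rows, ] <- drive[rows, ] +
      outer(gate, 0.4 * pmax(str$class_means[, cv_idx[r]], 0))
  }

  voltage <- matrix(0, n_total, n_e)
  env_truth <- list()

  # latent white noise per electrode; beta mixed with the high-gamma latent
  # at engaged electrodes (engagement pooled over CVs for the continuous
  # recording)
  eng_e <- apply(str$engagement, 1, max)
  rho_e <- ifelse(eng_e > 0.5, config$coupling_beta_hg, config$coupling_inactive)
  rho_le <- vapply(rho_e, latent_rho, numeric(1), s = s)
  w_hg <- matrix(stats::rnorm(n_total * n_e), n_total, n_e)
  z_hg <- smooth_standardize(w_hg, sd_samples)
  for (b in bands) {
    if (b == "high_gamma") {
      z <- z_hg
    } else if (b == "beta") {
      w <- sweep(w_hg, 2, rho_le, `*`) +
        sweep(matrix(stats::rnorm(n_total * n_e), n_total, n_e), 2,
              sqrt(1 - rho_le^2), `*`)
      z <- smooth_standardize(w, sd_samples)
    } else {
      z <- smooth_standardize(matrix(stats::rnorm(n_total * n_e), n_total, n_e),
                              sd_samples)
    }
    log_env <- s * z
    if (b == "high_gamma") log_env <- log_env + drive
    env <- envelope_base[[b]] * exp(log_env)
    env_truth[[b]] <- env
    phase <- stats::runif(n_e, 0, 2 * pi)
    carrier_wave <- outer(t_total, rep(2 * pi * band_carriers[[b]], n_e)) +
      matrix(phase, n_total, n_e, byrow = TRUE)
    voltage <- voltage + env * cos(carrier_wave)
  }

  # 1/f background
  pink <- apply(matrix(stats::rnorm(n_total * n_e), n_total, n_e), 2,
                function(x) {
    sp <- stats::fft(x)
    f <- c(1, seq_len(n_total - 1))
    f <- pmin(f, n_total - f + 1)
    sp <- sp / sqrt(f)
    re <- Re(stats::fft(sp, inverse = TRUE)) / n_total
    re / stats::sd(re)
  })
  voltage <- voltage + pink_sd * pink

  structure(list(
    voltage = voltage, fs = fs, event_times = event_times, labels = labels,
    baseline = c(0, config$baseline_s),
    truth = list(cvs = cvs, class_means = str$class_means,
                 engagement = str$engagement, active = str$active,
                 envelopes = env_truth, amap = amap, config = config)
  ), class = "cv_voltage")
}

#' Simulate a soft confusion matrix from the articulatory hierarchy
#'
#' Generates a row-stochastic soft confusion whose off-diagonal mass decays
#' with weighted articulatory feature distance between syllables,
#' `P(predicted | true) proportional to exp(-sum_g w_g d_g)`. With the
#' default weights the major-articulator blocks dominate, planting the
#' hierarchical block structure that the clustering analysis is designed to
#' recover. Multiplicative log-normal noise perturbs the rows before
#' renormalization.
#'
#' @param inventory A [make_inventory()].
#' @param weights Named non-negative weights per grouping.
#' @param noise Standard deviation of log-normal row noise (0 = noise-free).
#' @param seed Integer seed for the noise.
#' @return A `soft_confusion` matrix over the full inventory.
#' @export
simulate_soft_confusion <- function(inventory,
                                    weights = c(articulator = 4,
                                                location = 1,
                                                degree = 0.5,
                                                vowel = 0.5),
                                    noise = 0, seed = 1) {
  f <- inventory$features
  grp <- attr(f, "grouping")
  n <- nrow(f)
  D <- matrix(0, n, n)
  for (g in names(weights)) {
    D <- D + weights[[g]] *
      as.matrix(stats::dist(f[, grp == g, drop = FALSE]))
  }
  P <- exp(-D)
  if (noise > 0) {
    set.seed(seed)
    P <- P * exp(matrix(stats::rnorm(length(P), 0, noise), n, n))
  }
  P <- P / rowSums(P)
  dimnames(P) <- list(inventory$cvs, inventory$cvs)
  structure(P, class = c("soft_confusion", "matrix"))
}
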