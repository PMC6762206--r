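#' Z-score amplitudes to a quiescent baseline window
#'
#' Normalizes each channel by the mean and standard deviation of its
#' amplitude inside a baseline window (a silent, resting segment disjoint
#' from all trials).
#'
#' @param amplitude `[time x channel]` matrix (or vector) of non-negative
#'   envelopes, or a `[time x channel x filter]` array (each filter
#'   normalized independently).
#' @param fs Sampling rate, Hz.
#' @param baseline `c(start, end)` of the baseline window, s.
#' @return Z-scored amplitude of the same shape. Errors if the baseline is
#'   empty or any channel has zero baseline variance.
#' @export
zscore_baseline <- function(amplitude, fs, baseline) {
  stopifnot(length(baseline) == 2, baseline[2] > baseline[1])
  if (length(dim(amplitude)) == 3) {
    for (k in seq_len(dim(amplitude)[3])) {
      amplitude[, , k] <- zscore_baseline(amplitude[, , k], fs, baseline)
    }
    return(amplitude)
  }
  amplitude <- as.matrix(amplitude)
  rows <- seq(floor(baseline[1] * fs) + 1, floor(baseline[2] * fs))
  rows <- rows[rows >= 1 & rows <= nrow(amplitude)]
  if (length(rows) < 2) stop("baseline window is empty")
  mu <- colMeans(amplitude[rows, , drop = FALSE])
  sd <- apply(amplitude[rows, , drop = FALSE], 2, stats::sd)
  if (any(sd == 0)) stop("zero baseline variance in at least one channel")
  sweep(sweep(amplitude, 2, mu), 2, sd, `/`)
}

#' Average filter amplitudes into a canonical band
#'
#' Unweighted mean over the filters whose center frequencies fall inside the
#' band's range.
#'
#' @param amplitudes `[time x electrode x filter]` array of per-filter
#'   amplitudes.
#' @param fb The [design_filterbank()] that produced them.
#' @param band Band name (see [canonical_bands()]) or a numeric
#'   `c(f_lo, f_hi)` range, Hz.
#' @return `[time x electrode]` matrix. Errors if no filter falls in the
#'   band.
#' @export
aggregate_to_band <- function(amplitudes, fb, band) {
  rng <- if (is.character(band)) band_range(band) else band
  keep <- which(fb$center >= rng[1] & fb$center <= rng[2])
  if (length(keep) == 0) stop("no filter center inside band [",
                              rng[1], ", ", rng[2], "] Hz")
  out <- amplitudes[, , keep[1], drop = FALSE][, , 1]
  if (length(keep) > 1) {
    for (k in keep[-1]) out <- out + amplitudes[, , k]
    out <- out / length(keep)
  }
  as.matrix(out)
}

#' Best rational approximation p/q with bounded denominator
#' @noRd
rational_approx <- function(r, max_den = 1000) {
  q <- seq_len(max_den)
  p <- round(r * q)
  err <- abs(p / q - r)
  i <- which.min(err)
  c(p = p[i], q = q[i])
}

#' Downsample a band to a constant center-frequency-to-rate ratio
#'
#' Resamples a band's amplitude so that `center / fs` matches the high-gamma
#' reference ratio 112.5/200 -- lower bands are heavily oversampled at
#' 200 Hz, and equalizing the ratio makes cross-band decoding comparisons
#' interpretable. Polyphase resampling with a rational approximation of the
#' rate ratio (denominator at most `max_den`).
#'
#' @param amplitude `[time x channel]` matrix (or vector).
#' @param fs Input sampling rate, Hz.
#' @param band_center Band center frequency, Hz (at most the 112.5 Hz
#'   high-gamma reference).
#' @param ratio Target center-to-rate ratio (default `112.5 / 200`).
#' @param max_den Maximum denominator for the rational rate approximation.
#' @return List with `values` (`[time x channel]` at the new rate) and `fs`
#'   (realized output rate, Hz). The high-gamma reference itself passes
#'   through unchanged.
#' @export
downsample_constant_ratio <- function(amplitude, fs, band_center,
                                      ratio = 112.5 / 200, max_den = 1000) {
  target_fs <- band_center / ratio
  if (target_fs > fs) stop("band_center implies upsampling; expected <= ",
                           fs * ratio, " Hz")
  amplitude <- as.matrix(amplitude)
  if (isTRUE(all.equal(target_fs, fs))) {
    return(list(values = amplitude, fs = fs))
  }
  pq <- rational_approx(target_fs / fs, max_den)
  values <- apply(amplitude, 2, function(col) {
    signal::resample(col, pq[["p"]], pq[["q"]])
  })
  list(values = as.matrix(values), fs = fs * pq[["p"]] / pq[["q"]])
}

#' Number of samples in the trial window
#'
#' @param fs Sampling rate, Hz.
#' @param window `c(pre_s, post_s)` around the alignment event.
#' @return Integer sample count, `round(fs * (pre_s + post_s))` -- 258 for
#'   the default 200 Hz, (0.5, 0.79) s window.
#' @export
window_samples <- function(fs, window = c(0.5, 0.79)) {
  as.integer(round(fs * sum(window)))
}

#' Extract and edge-normalize one trial window
#'
#' Cuts the half-open sample window `[event - pre_s, event + post_s)` from a
#' continuous amplitude record and subtracts, per channel, the mean of the
#' first and last ~4% of samples (`floor(0.04 * n)`, at least 1, per edge) --
#' a local amplitude normalization.
#'
#' @param amplitude `[time x channel]` matrix (or vector).
#' @param fs Sampling rate, Hz.
#' @param event_time Alignment event time, s (0 = first sample).
#' @param window `c(pre_s, post_s)`, s.
#' @param edge_frac Fraction of samples per edge used for the normalization
#'   mean (default 0.04).
#' @return `[n x channel]` matrix with `n = window_samples(fs, window)`.
#'   Errors if the window falls outside the record.
#' @export
extract_trial_window <- function(amplitude, fs, event_time,
                                 window = c(0.5, 0.79), edge_frac = 0.04) {
  amplitude <- as.matrix(amplitude)
  n <- window_samples(fs, window)
  start <- round((event_time - window[1]) * fs) + 1
  if (start < 1 || start + n - 1 > nrow(amplitude)) {
    stop("trial window [", start, ", ", start + n - 1,
         "] outside the record (", nrow(amplitude), " samples)")
  }
  seg <- amplitude[start + seq_len(n) - 1, , drop = FALSE]
  k <- max(1L, floor(edge_frac * n))
  edges <- c(seq_len(k), n - k + seq_len(k))
  sweep(seg, 2, colMeans(seg[edges, , drop = FALSE]))
}

#' Assemble a trial tensor from a continuous record
#'
#' @param amplitude `[time x electrode]` matrix.
#' @param fs Sampling rate, Hz.
#' @param event_times Numeric vector of alignment events, s.
#' @param window,edge_frac Passed to [extract_trial_window()].
#' @return Array `[trial x electrode x time]`.
#' @export
extract_trials <- function(amplitude, fs, event_times,
                           window = c(0.5, 0.79), edge_frac = 0.04) {
  n <- window_samples(fs, window)
  out <- array(0, dim = c(length(event_times), ncol(as.matrix(amplitude)), n))
  for (r in seq_along(event_times)) {
    out[r, , ] <- t(extract_trial_window(amplitude, fs, event_times[r],
                                         window, edge_frac))
  }
  out
}
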