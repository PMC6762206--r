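#' Gaussian bandpass filterbank with geometric center spacing
#'
#' Designs the 40-filter bank used for time-frequency decomposition:
#' center frequencies geometrically spaced on `[f_lo, f_hi]` and Gaussian
#' frequency-domain bandwidths that increase semi-logarithmically --
#' log-linear interpolation from 1.5 Hz at the lowest center up to `cf / 7`
#' at 40 Hz, and `cf / 7` above. Equivalent to a frequency-domain Morlet
#' wavelet with a frequency-dependent quality factor.
#'
#' @param n Number of filters (default 40).
#' @param f_lo,f_hi Lowest and highest center frequencies, Hz.
#' @return A `filterbank`: data frame with columns `center` (strictly
#'   increasing, Hz) and `bw_sd` (Gaussian standard deviation, Hz).
#' @examples
#' fb <- design_filterbank()
#' sum(fb$center >= 70 & fb$center <= 150)  # filters averaged into high gamma
#' @export
design_filterbank <- function(n = 40, f_lo = 4.07, f_hi = 193.2) {
  if (f_lo <= 0 || f_hi <= f_lo) stop("need 0 < f_lo < f_hi")
  center <- f_lo * (f_hi / f_lo)^((seq_len(n) - 1) / (n - 1))
  bw_at <- function(cf) {
    lo_bw <- 1.5
    hi_cf <- 40
    ifelse(cf >= hi_cf, cf / 7,
           lo_bw + (hi_cf / 7 - lo_bw) *
             (log(cf) - log(f_lo)) / (log(hi_cf) - log(f_lo)))
  }
  structure(data.frame(center = center, bw_sd = bw_at(center)),
            class = c("filterbank", "data.frame"))
}

#' Canonical neuroscience frequency bands
#'
#' @return Data frame with `name`, `f_lo`, `f_hi` (Hz) for theta `[4,7]`,
#'   alpha `[8,14]`, beta `[15,29]`, gamma `[30,59]` and high gamma
#'   `[70,150]`.
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma", "high_gamma"),
    f_lo = c(4, 8, 15, 30, 70),
    f_hi = c(7, 14, 29, 59, 150)
  )
}

band_range <- function(band) {
  cb <- canonical_bands()
  i <- match(band, cb$name)
  if (is.na(i)) stop("unknown band: ", band)
  c(cb$f_lo[i], cb$f_hi[i])
}

#' Analytic amplitude through one Gaussian bandpass filter
#'
#' Computes the time-varying envelope of `x` in one filter: the spectrum is
#' made analytic (negative frequencies zeroed, positive doubled), weighted
#' by a Gaussian centered at `center` with standard deviation `bw_sd`, and
#' the magnitude of the inverse transform is returned.
#'
#' @param x Numeric vector or `[time x channel]` matrix.
#' @param fs Sampling rate, Hz.
#' @param center,bw_sd Filter center frequency and Gaussian bandwidth, Hz.
#'   `center` must lie below the Nyquist frequency.
#' @return Non-negative envelope, same shape as `x`.
#' @export
analytic_amplitude <- function(x, fs, center, bw_sd) {
  if (center >= fs / 2) stop("filter center above Nyquist frequency")
  x <- as.matrix(x)
  n <- nrow(x)
  freqs <- (seq_len(n) - 1) / n * fs
  weight <- 2 * exp(-0.5 * ((freqs - center) / bw_sd)^2)
  weight[freqs > fs / 2] <- 0          # analytic: kill negative frequencies
  weight[1] <- weight[1] / 2
  if (n %% 2 == 0) weight[n / 2 + 1] <- weight[n / 2 + 1] / 2
  sp <- stats::mvfft(x) * weight
  out <- Mod(stats::mvfft(sp, inverse = TRUE)) / n
  if (is.null(dim(x)) || ncol(x) == 1) out <- drop(out)
  out
}

#' Full filterbank amplitude decomposition
#'
#' @param voltage `[time x electrode]` matrix.
#' @param fs Sampling rate, Hz.
#' @param fb A [design_filterbank()] object.
#' @return Array `[time x electrode x filter]` of analytic amplitudes.
#' @export
filter_amplitudes <- function(voltage, fs, fb = design_filterbank()) {
  voltage <- as.matrix(voltage)
  out <- array(0, dim = c(nrow(voltage), ncol(voltage), nrow(fb)))
  for (k in seq_len(nrow(fb))) {
    out[, , k] <- analytic_amplitude(voltage, fs, fb$center[k], fb$bw_sd[k])
  }
  out
}

#' Downsample and common-average reference raw voltage
#'
#' Removes bad channels, downsamples to `fs_out` in the frequency domain
#' (spectral truncation), and subtracts the per-sample mean across the
#' retained channels.
#'
#' @param voltage `[time x channel]` matrix.
#' @param fs_raw Input sampling rate, Hz (`>= fs_out`).
#' @param bad_channels Integer indices of channels to drop.
#' @param fs_out Output rate, Hz (default 400).
#' @return `[time x channel]` matrix at `fs_out`, referenced.
#' @export
preprocess_voltage <- function(voltage, fs_raw, bad_channels = integer(0),
                               fs_out = 400) {
  voltage <- as.matrix(voltage)
  if (fs_raw < fs_out) stop("fs_raw must be >= fs_out")
  if (length(bad_channels) > 0) {
    voltage <- voltage[, -bad_channels, drop = FALSE]
  }
  if (ncol(voltage) == 0) stop("all channels marked bad")
  if (fs_raw > fs_out) {
    n <- nrow(voltage)
    n_new <- round(n * fs_out / fs_raw)
    sp <- stats::mvfft(voltage)
    keep_lo <- ceiling(n_new / 2)              # positive freqs incl. DC
    keep_hi <- n_new - keep_lo                 # negative freqs
    sp_new <- rbind(sp[seq_len(keep_lo), , drop = FALSE],
                    sp[n - keep_hi + seq_len(keep_hi), , drop = FALSE])
    voltage <- Re(stats::mvfft(sp_new, inverse = TRUE)) / n
  }
  sweep(voltage, 1, rowMeans(voltage))
}
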