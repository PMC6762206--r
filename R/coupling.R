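#' Trial-average an amplitude tensor per syllable
#'
#' @param amplitudes `[trial x electrode x time]` array.
#' @param labels Trial labels (every retained class needs at least one
#'   trial).
#' @param classes Class order of the output (default: sorted unique labels).
#' @return Array `[class x electrode x time]` with class dimnames.
#' @export
trial_average <- function(amplitudes, labels, classes = NULL) {
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(classes %in% labels)) {
    stop("class without trials: ",
         paste(setdiff(classes, labels), collapse = ", "))
  }
  out <- array(0, dim = c(length(classes), dim(amplitudes)[2],
                          dim(amplitudes)[3]),
               dimnames = list(classes, NULL, NULL))
  for (k in seq_along(classes)) {
    rows <- which(labels == classes[k])
    sub <- amplitudes[rows, , , drop = FALSE]
    out[k, , ] <- apply(sub, c(2, 3), mean)
  }
  out
}

#' Trial-averaged tensor over a frequency axis
#'
#' Stacks per-band (or per-filter) trial averages into the data tensor
#' `D[class x frequency x electrode x time]` that the cross-frequency
#' analysis works on.
#'
#' @param dataset A [simulate_amplitude_dataset()] `cv_dataset`, or a named
#'   list of `[trial x electrode x time]` arrays plus `labels`.
#' @param labels Required when `dataset` is a plain list of arrays.
#' @return List with `D` (`[class x frequency x electrode x time]`),
#'   `frequency` (band names), `classes`.
#' @export
trial_average_tensor <- function(dataset, labels = NULL) {
  if (inherits(dataset, "cv_dataset")) {
    bands <- dataset$amplitudes
    labels <- dataset$labels
  } else {
    bands <- dataset
    if (is.null(labels)) stop("labels required")
  }
  classes <- sort(unique(as.character(labels)))
  avg <- lapply(bands, trial_average, labels = labels, classes = classes)
  d1 <- dim(avg[[1]])
  D <- array(0, dim = c(length(classes), length(avg), d1[2], d1[3]),
             dimnames = list(classes, names(bands), NULL, NULL))
  for (k in seq_along(avg)) D[, k, , ] <- avg[[k]]
  list(D = D, frequency = names(bands), classes = classes)
}

#' Average a trial-averaged tensor over a frequency band
#'
#' Unweighted mean over the frequency-axis entries whose center frequencies
#' fall inside the band.
#'
#' @param D `[class x frequency x electrode x time]` array.
#' @param centers Center frequency (Hz) of each frequency-axis entry.
#' @param band Band name or `c(f_lo, f_hi)` range, Hz.
#' @return `[class x electrode x time]` array.
#' @export
band_average <- function(D, centers, band) {
  rng <- if (is.character(band)) band_range(band) else band
  keep <- which(centers >= rng[1] & centers <= rng[2])
  if (length(keep) == 0) stop("no frequency entry inside the band")
  out <- D[, keep[1], , , drop = FALSE]
  dim(out) <- dim(D)[c(1, 3, 4)]
  if (length(keep) > 1) {
    for (k in keep[-1]) {
      sl <- D[, k, , , drop = FALSE]
      dim(sl) <- dim(D)[c(1, 3, 4)]
      out <- out + sl
    }
    out <- out / length(keep)
  }
  dimnames(out)[[1]] <- dimnames(D)[[1]]
  out
}

# Zero-lag Pearson correlations across time between one frequency entry and
# the reference, per (electrode, class) pair. Returns electrode x class.
pair_correlation <- function(x, reference) {
  n_cv <- dim(x)[1]; n_e <- dim(x)[2]
  C <- matrix(NA_real_, n_e, n_cv,
              dimnames = list(NULL, dimnames(x)[[1]]))
  for (j in seq_len(n_cv)) {
    for (i in seq_len(n_e)) {
      a <- x[j, i, ]; b <- reference[j, i, ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      C[i, j] <- stats::cor(a, b)
    }
  }
  C
}

#' Cross-frequency correlation spectrum against a reference band
#'
#' For each frequency-axis entry, the zero-lag Pearson correlation across
#' time between its trial-averaged envelope and the reference envelope is
#' computed per (electrode, class) pair, then averaged (with standard
#' error) over the pairs in `mask`. Pairs with a zero-variance series are
#' excluded and counted.
#'
#' @param D `[class x frequency x electrode x time]` array (at least 3 time
#'   samples).
#' @param centers Frequency-axis center frequencies, Hz.
#' @param reference `[class x electrode x time]` reference envelope
#'   (typically [band_average()] over high gamma).
#' @param mask Optional `[electrode x class]` logical matrix selecting
#'   pairs (default all).
#' @return Data frame with `center`, `mean_r`, `sem`, `n_pairs`,
#'   `n_excluded`.
#' @export
correlation_spectrum <- function(D, centers, reference, mask = NULL) {
  if (dim(D)[4] < 3) stop("need at least 3 time samples")
  rows <- lapply(seq_along(centers), function(k) {
    x <- D[, k, , , drop = FALSE]
    dim(x) <- dim(D)[c(1, 3, 4)]
    dimnames(x) <- dimnames(D)[c(1, 3, 4)]
    C <- pair_correlation(x, reference)
    sel <- if (is.null(mask)) rep(TRUE, length(C)) else as.vector(mask)
    vals <- as.vector(C)[sel]
    excluded <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    data.frame(center = centers[k], mean_r = mean(vals),
               sem = stats::sd(vals) / sqrt(length(vals)),
               n_pairs = length(vals), n_excluded = excluded)
  })
  do.call(rbind, rows)
}

#' Mean high-gamma amplitude in the peri-transition window
#'
#' Time-mean of the z-scored reference envelope in a half-open window
#' `[start, end)` around the consonant-to-vowel acoustic transition
#' (default 70 ms before to 140 ms after -- the most active and informative
#' period; 42 samples at 200 Hz).
#'
#' @param reference `[class x electrode x time]` trial-averaged envelope.
#' @param t Time axis, s (0 = transition), length matching the tensor.
#' @param window `c(start, end)` of the averaging window, s.
#' @return `[electrode x class]` matrix of mean amplitudes.
#' @export
hg_power_window <- function(reference, t, window = c(-0.070, 0.140)) {
  stopifnot(length(t) == dim(reference)[3])
  keep <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  if (length(keep) == 0) stop("power window outside the trial extent")
  A <- apply(reference[, , keep, drop = FALSE], c(1, 2), mean)
  t(A)   # electrode x class
}

#' Activity threshold from the correlation-versus-power fit
#'
#' Ordinary least-squares fit of the per-pair band-to-reference correlation
#' `C` on the per-pair mean reference amplitude `A`, restricted to pairs
#' with above-baseline amplitude (`A > 0`). The activity threshold is the
#' amplitude at which the fit predicts zero correlation,
#' `A_thresh = -intercept / slope`; pairs above it form the active group.
#'
#' @param C `[electrode x class]` correlations (or vector).
#' @param A `[electrode x class]` mean amplitudes (same shape).
#' @param slope_tol Slopes smaller than this in absolute value make the
#'   threshold undefined (degenerate flag).
#' @return An `activity_split`: list with `slope`, `intercept`,
#'   `threshold`, `active` (logical, same shape as `A`), `n_fit`,
#'   `degenerate`.
#' @export
fit_activity_threshold <- function(C, A, slope_tol = 1e-8) {
  stopifnot(length(C) == length(A))
  sel <- which(A > 0 & is.finite(C) & is.finite(A))
  if (length(sel) < 2) stop("fewer than 2 pairs with positive amplitude")
  fit <- stats::lm(c(C)[sel] ~ c(A)[sel])
  b <- unname(stats::coef(fit)[1])
  m <- unname(stats::coef(fit)[2])
  degenerate <- !is.finite(m) || abs(m) < slope_tol
  threshold <- if (degenerate) NA_real_ else -b / m
  active <- if (degenerate) array(NA, dim = dim(A) %||% length(A)) else
    A > threshold
  structure(list(slope = m, intercept = b, threshold = threshold,
                 active = active, n_fit = length(sel),
                 degenerate = degenerate),
            class = "activity_split")
}

#' Correlation spectra resolved by activity group
#'
#' Evaluates the cross-frequency correlation spectrum separately for the
#' active and inactive (electrode, class) pairs of an [fit_activity_threshold()]
#' split, and summarizes the (amplitude, correlation) cloud in nine
#' equal-count amplitude bins.
#'
#' @param D,centers,reference As in [correlation_spectrum()].
#' @param split An `activity_split`.
#' @param C,A Per-pair correlation and amplitude matrices used for the
#'   binned summary (e.g. the inputs to the split fit).
#' @param n_bins Number of equal-count amplitude bins (default 9).
#' @return List with `active`, `inactive` (spectra data frames; `NULL` with
#'   a message element if a group is empty) and `bins` (data frame:
#'   bin mean amplitude, mean correlation, sem, count).
#' @export
grouped_correlation_spectra <- function(D, centers, reference, split,
                                        C = NULL, A = NULL, n_bins = 9) {
  stopifnot(inherits(split, "activity_split"))
  if (split$degenerate) stop("degenerate split: threshold undefined")
  act <- split$active
  spectra <- list(
    active = if (any(act)) correlation_spectrum(D, centers, reference,
                                                mask = act) else NULL,
    inactive = if (any(!act)) correlation_spectrum(D, centers, reference,
                                                   mask = !act) else NULL
  )
  bins <- NULL
  if (!is.null(C) && !is.null(A)) {
    ok <- is.finite(C) & is.finite(A)
    a <- c(A)[ok]; cc <- c(C)[ok]
    qs <- stats::quantile(a, probs = seq(0, 1, length.out = n_bins + 1))
    grp <- cut(a, breaks = unique(qs), include.lowest = TRUE)
    bins <- data.frame(
      mean_amplitude = tapply(a, grp, mean),
      mean_r = tapply(cc, grp, mean),
      sem = tapply(cc, grp, function(v) stats::sd(v) / sqrt(length(v))),
      count = as.integer(table(grp))
    )
    rownames(bins) <- NULL
  }
  c(spectra, list(bins = bins))
}
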