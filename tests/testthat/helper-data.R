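# Shared fixtures, all generated in code.

# Balanced XOR arrangement: two classes, each split across two diagonal
# Gaussian clusters, with a cluster id for stratified splitting.
xor_dataset <- function(n_per_cluster = 60, sd = 0.2, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  x <- do.call(rbind, lapply(1:4, function(k) {
    cbind(stats::rnorm(n_per_cluster, centers[k, 1], sd),
          stats::rnorm(n_per_cluster, centers[k, 2], sd))
  }))
  list(x = x,
       y = rep(c("same", "same", "diff", "diff"), each = n_per_cluster),
       cluster = rep(1:4, each = n_per_cluster))
}

# Two well-separated Gaussian classes.
gaussian_dataset <- function(n_per_class = 120, delta = 4, seed = 7) {
  set.seed(seed)
  x <- rbind(cbind(stats::rnorm(n_per_class, delta / 2), stats::rnorm(n_per_class)),
             cbind(stats::rnorm(n_per_class, -delta / 2), stats::rnorm(n_per_class)))
  list(x = x, y = rep(c("p", "q"), each = n_per_class))
}

# Adjusted Rand index oracle (mclust) with a plain fallback signature.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Per-pair beta/high-gamma correlation and window amplitude from a
# simulated amplitude dataset.
coupling_measurements <- function(ds) {
  ta <- trial_average_tensor(ds)
  centers <- c(beta = 22, high_gamma = 110)[ta$frequency]
  ref <- band_average(ta$D, centers, "high_gamma")
  beta <- band_average(ta$D, centers, "beta")
  C <- ecogcv:::pair_correlation(beta, ref)
  A <- hg_power_window(ref, ds$t)
  act <- ds$truth$active[, match(ta$classes, ds$truth$cvs), drop = FALSE]
  list(C = C, A = A, active = act, ta = ta, ref = ref, centers = centers)
}
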