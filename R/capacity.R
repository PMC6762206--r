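#' Confusion model: conditional P(predicted | true) plus class prior
#'
#' Validates and wraps a conditional probability table (rows = true class,
#' columns = predicted class, each row summing to 1) together with a prior
#' over true classes. This is the substrate for mutual information and
#' channel capacity.
#'
#' @param conditional `[class x class]` non-negative matrix with unit row
#'   sums. Rows of all zeros are rejected.
#' @param prior Prior over true classes (default uniform); must sum to 1.
#' @return An object of class `confusion_model`.
#' @export
confusion_model <- function(conditional, prior = NULL) {
  conditional <- as.matrix(conditional)
  if (any(conditional < 0)) stop("negative conditional probabilities")
  rs <- rowSums(conditional)
  if (any(rs == 0)) stop("conditional rows of all zeros are not allowed")
  if (any(abs(rs - 1) > 1e-9)) stop("conditional rows must sum to 1")
  n <- nrow(conditional)
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (length(prior) != n || any(prior < 0) || abs(sum(prior) - 1) > 1e-9) {
    stop("prior must be a length-", n, " distribution")
  }
  structure(list(conditional = conditional, prior = as.numeric(prior),
                 n_classes = n),
            class = "confusion_model")
}

#' Empirical confusion model from pooled test predictions
#'
#' Builds the conditional table from per-fold test predictions pooled across
#' folds; the prior is the empirical class frequency of the true labels.
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Class levels (default: sorted union).
#' @return A [confusion_model()]. Errors if any class has zero test trials.
#' @export
confusion_from_predictions <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  counts <- table(factor(true, classes), factor(predicted, classes))
  if (any(rowSums(counts) == 0)) {
    stop("class with zero test trials: ",
         paste(classes[rowSums(counts) == 0], collapse = ", "))
  }
  conditional <- sweep(unclass(counts), 1, rowSums(counts), `/`)
  confusion_model(conditional, prior = as.numeric(rowSums(counts)) /
                    length(true))
}

# 0 * log 0 = 0 throughout
xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Mutual information of a confusion model, bits per symbol
#'
#' `I = sum_y sum_yhat P(y) P(yhat|y) log2[P(yhat|y) / P(yhat)]` with
#' `P(yhat) = sum_y P(y) P(yhat|y)` and `0 log 0 = 0`.
#'
#' @param conf A [confusion_model()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(conf) {
  stopifnot(inherits(conf, "confusion_model"))
  w <- conf$conditional
  p <- conf$prior
  q <- as.numeric(p %*% w)
  lq <- log2(pmax(q, .Machine$double.xmin))
  lw <- log2(pmax(w, .Machine$double.xmin))
  per_row <- rowSums(w * (lw - rep(lq, each = nrow(w))) * (w > 0))
  sum(p * per_row)
}

#' Exact channel capacity by alternating maximization
#'
#' Computes `CC = sup_{P(Y)} I(Yhat; Y)` for a fixed conditional table by
#' Blahut-Arimoto alternating maximization, iterating until the standard
#' upper and lower capacity bounds differ by less than `tol`. The lower
#' bound is non-decreasing over iterations.
#'
#' @param conf A [confusion_model()] (its prior seeds the iteration) or a
#'   valid conditional matrix.
#' @param tol Bound-gap stopping tolerance, bits (default 1e-10).
#' @param max_iter Iteration cap; exceeding it is an error
#'   (non-convergence).
#' @return List with `bits` (capacity), `prior` (maximizing input
#'   distribution), `iterations`, `gap`, and `trace` (lower-bound sequence).
#' @export
channel_capacity_exact <- function(conf, tol = 1e-10, max_iter = 1e5) {
  if (!inherits(conf, "confusion_model")) conf <- confusion_model(conf)
  w <- conf$conditional
  p <- conf$prior
  p[p == 0] <- .Machine$double.eps      # supremum needs open support
  p <- p / sum(p)
  lw <- log2(pmax(w, .Machine$double.xmin))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    q <- as.numeric(p %*% w)
    lq <- log2(pmax(q, .Machine$double.xmin))
    d <- rowSums(w * (lw - rep(lq, each = nrow(w))) * (w > 0))
    lower <- sum(p * d)
    upper <- max(d)
    trace <- c(trace, lower)
    if (upper - lower < tol) {
      return(list(bits = lower, prior = p, iterations = it,
                  gap = upper - lower, trace = trace))
    }
    p <- p * 2^(d - max(d))
    p <- p / sum(p)
  }
  stop("alternating maximization did not converge in ", max_iter,
       " iterations (gap ", signif(upper - lower, 3), " bits)")
}

#' Uniform-error (Wolpaw) channel capacity approximation
#'
#' Assumes every class has the mean accuracy `p` and all errors are spread
#' uniformly over the remaining `n - 1` classes:
#' `log2(N) + P log2 P + (1 - P) log2[(1 - P)/(N - 1)]`, with `0 log 0 = 0`.
#' On genuinely symmetric channels this equals the exact capacity; on real
#' speech confusions (structured errors) it generally does not.
#'
#' @param accuracy Mean accuracy `P` in `[0, 1]`.
#' @param n_classes Number of classes `N >= 2`.
#' @return Capacity approximation, bits per symbol.
#' @examples
#' wolpaw_capacity(0.361, 24)  # 0.75 to 2 d.p.
#' @export
wolpaw_capacity <- function(accuracy, n_classes) {
  stopifnot(accuracy >= 0, accuracy <= 1, n_classes >= 2)
  log2(n_classes) + xlog2(accuracy) +
    (1 - accuracy) * (log2(pmax(1 - accuracy, .Machine$double.xmin)) -
                        log2(n_classes - 1)) * (accuracy < 1)
}

#' Information transfer rate
#'
#' Channel capacity divided by the symbol duration.
#'
#' @param capacity_bits Capacity, bits per symbol.
#' @param symbol_duration_s Symbol duration, s (> 0).
#' @return Bits per second.
#' @export
itr <- function(capacity_bits, symbol_duration_s) {
  if (symbol_duration_s <= 0) stop("symbol duration must be positive")
  capacity_bits / symbol_duration_s
}

#' Capacity summary of a confusion model
#'
#' @param conf A [confusion_model()].
#' @param symbol_duration_s Symbol duration for the transfer rate, s
#'   (default 1.3).
#' @return List with `mi_bits`, `capacity_exact_bits`,
#'   `capacity_wolpaw_bits` (at the model's mean accuracy under its prior),
#'   `itr_bits_per_s`.
#' @export
capacity_estimate <- function(conf, symbol_duration_s = 1.3) {
  stopifnot(inherits(conf, "confusion_model"))
  acc <- sum(conf$prior * diag(conf$conditional))
  cc <- channel_capacity_exact(conf)
  list(mi_bits = mutual_information(conf),
       capacity_exact_bits = cc$bits,
       capacity_wolpaw_bits = wolpaw_capacity(acc, conf$n_classes),
       itr_bits_per_s = itr(cc$bits, symbol_duration_s))
}
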