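#' Stratified cross-validation folds with mutually exclusive test sets
#'
#' Organizes trials into `n_folds` groupings with 80-10-10 train /
#' validation / test splits, each class represented proportionally in every
#' set. Test sets are mutually exclusive across folds (their union is the
#' set of retained trials). Classes with fewer than `min_class` examples are
#' excluded.
#'
#' @param labels Trial label vector.
#' @param n_folds Number of folds (default 10).
#' @param min_class Minimum class size to retain (default 10).
#' @param seed Integer seed for the within-class shuffles.
#' @return A list of class `fold_splits`: per fold, `train`, `validation`,
#'   `test` index vectors; plus attributes `kept` (retained trial indices)
#'   and `dropped_classes`.
#' @export
make_folds <- function(labels, n_folds = 10, min_class = 10, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  keep_classes <- names(tab)[tab >= min_class]
  if (length(keep_classes) == 0) stop("no class has >= ", min_class, " trials")
  kept <- which(labels %in% keep_classes)

  set.seed(seed)
  chunks <- vector("list", n_folds)
  for (f in seq_len(n_folds)) chunks[[f]] <- integer(0)
  for (cl in keep_classes) {
    idx <- sample(which(labels == cl))
    assign_to <- rep(seq_len(n_folds), length.out = length(idx))
    for (f in seq_len(n_folds)) {
      chunks[[f]] <- c(chunks[[f]], idx[assign_to == f])
    }
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    val_f <- if (f == n_folds) 1L else f + 1L
    test <- sort(chunks[[f]])
    validation <- sort(chunks[[val_f]])
    train <- sort(setdiff(kept, c(test, validation)))
    list(fold = f, train = train, validation = validation, test = test)
  })
  structure(folds, class = "fold_splits", kept = sort(kept),
            dropped_classes = setdiff(names(tab), keep_classes))
}

#' Chance accuracy by resampling the training label distribution
#'
#' Estimates chance by drawing test-set predictions i.i.d. from the training
#' label frequencies and averaging the resulting accuracy over
#' `n_resamples` resamplings. Its expectation is `sum_i p_i q_i` for train
#' frequencies `p` and test frequencies `q`.
#'
#' @param train_labels,test_labels Label vectors.
#' @param n_resamples Number of resamplings (default 100).
#' @param seed Integer seed.
#' @return List with `chance` (mean accuracy) and `resamples` (per-resample
#'   accuracies, for interval checks).
#' @export
estimate_chance <- function(train_labels, test_labels, n_resamples = 100,
                            seed = 1) {
  stopifnot(length(train_labels) > 0, length(test_labels) > 0)
  set.seed(seed)
  train_labels <- as.character(train_labels)
  test_labels <- as.character(test_labels)
  acc <- vapply(seq_len(n_resamples), function(i) {
    pred <- sample(train_labels, length(test_labels), replace = TRUE)
    mean(pred == test_labels)
  }, numeric(1))
  list(chance = mean(acc), resamples = acc)
}

#' Default random-search space over classifier hyperparameters
#'
#' Architecture and optimization ranges spanning the regularizers the
#' trainer supports: 1-3 hidden layers (or 0 for the logistic family),
#' widths log-uniform on `[32, 1024]`, tanh or rectifier nonlinearity,
#' initial learning rate log-uniform on `[1e-4, 1e-1]` with per-epoch decay
#' in `[0.95, 1]` and floor `1e-6`, momentum saturation in `[0.9, 0.99]`,
#' dropout in `[0, 0.7]`, weight decay log-uniform on `[1e-7, 1e-2]`,
#' max-norm in `[0.5, 4]`, batch size in `{32, 64, 128}`.
#'
#' @param deep If `FALSE` the number of hidden layers is fixed at 0 and
#'   hidden-layer hyperparameters are unused.
#' @param max_epochs,patience Passed through to every draw.
#' @return A function `(void) -> hp` drawing one hyperparameter setting
#'   from the space (uses the current RNG stream).
#' @export
default_search_space <- function(deep = TRUE, max_epochs = 100,
                                 patience = 10) {
  function() {
    n_hidden <- if (deep) sample(1:3, 1) else 0L
    hidden <- if (n_hidden > 0) {
      as.integer(round(exp(stats::runif(n_hidden, log(32), log(1024)))))
    } else integer(0)
    default_hp(
      hidden = hidden,
      activation = sample(c("tanh", "relu"), 1),
      lr = exp(stats::runif(1, log(1e-4), log(1e-1))),
      lr_decay = stats::runif(1, 0.95, 1),
      lr_floor = 1e-6,
      momentum_sat = stats::runif(1, 0.9, 0.99),
      dropout = if (deep) stats::runif(1, 0, 0.7) else 0,
      weight_decay = exp(stats::runif(1, log(1e-7), log(1e-2))),
      max_norm = stats::runif(1, 0.5, 4),
      batch_size = sample(c(32L, 64L, 128L), 1),
      max_epochs = max_epochs, patience = patience
    )
  }
}

#' Random hyperparameter search across folds
#'
#' Draws `n_draws` hyperparameter settings, trains each on every fold, and
#' selects the draw with the best mean validation accuracy (ties broken by
#' lowest draw index). Deterministic under a fixed seed.
#'
#' @param x `[n x p]` features; `y` labels.
#' @param folds A [make_folds()] object.
#' @param space A draw function as returned by [default_search_space()].
#' @param n_draws Number of draws (default 400).
#' @param seed Integer seed.
#' @return List with `best_hp`, `best_index`, `best_validation`, and
#'   `record` (data frame of per-draw mean validation accuracy).
#' @export
random_search <- function(x, y, folds, space = default_search_space(),
                          n_draws = 400, seed = 1) {
  classes <- sort(unique(as.character(y)))
  set.seed(seed)
  draws <- replicate(n_draws, space(), simplify = FALSE)
  val_acc <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    accs <- vapply(seq_along(folds), function(f) {
      fit <- train_classifier(x[folds[[f]]$train, , drop = FALSE],
                              y[folds[[f]]$train], hp = draws[[d]],
                              x_val = x[folds[[f]]$validation, , drop = FALSE],
                              y_val = y[folds[[f]]$validation],
                              classes = classes,
                              seed = seed + 1000L * d + f)
      fit$validation_accuracy
    }, numeric(1))
    val_acc[d] <- mean(accs)
  }
  best <- which.max(val_acc)   # first index wins ties
  list(best_hp = draws[[best]], best_index = best,
       best_validation = val_acc[best],
       record = data.frame(draw = seq_len(n_draws),
                           mean_validation_accuracy = val_acc))
}

#' Accuracy of syllable predictions under a restricted task
#'
#' Maps both predictions and ground truth through a task labeling
#' (consonant, vowel, constriction location or degree) and scores accuracy
#' on the mapped labels. Trials whose true syllable lies outside a
#' restricted task are dropped; predictions outside the task count as
#' errors. If every prediction falls outside the restricted task the result
#' is flagged degenerate (chance is undefined there).
#'
#' @param pred_cv,true_cv Character vectors of predicted and true CV labels.
#' @param inventory A [make_inventory()].
#' @param task Task name, see [task_labels()].
#' @return List with `accuracy`, `n` (scored trials), `task`, and
#'   `degenerate`.
#' @export
restricted_accuracy <- function(pred_cv, true_cv, inventory,
                                task = c("cv", "consonant", "vowel",
                                         "location", "degree")) {
  task <- match.arg(task)
  true_m <- task_labels(inventory, task, as.character(true_cv))
  pred_m <- task_labels(inventory, task, as.character(pred_cv))
  inside <- !is.na(true_m)
  if (!any(inside)) stop("no trial belongs to the restricted task")
  true_m <- true_m[inside]
  pred_m <- pred_m[inside]
  degenerate <- all(is.na(pred_m))
  correct <- !is.na(pred_m) & pred_m == true_m
  list(accuracy = mean(correct), n = sum(inside), task = task,
       degenerate = degenerate)
}

#' Time-resolved decoding with per-timepoint logistic models
#'
#' Trains an independent multinomial logistic model at each time sample
#' (features = all electrodes at that sample) and reports per-time test
#' accuracy with its standard error across folds.
#'
#' @param amplitudes `[trial x electrode x time]` array.
#' @param labels Trial labels.
#' @param folds A [make_folds()] object.
#' @param hp Hyperparameters (default: logistic regression).
#' @param seed Integer seed.
#' @return Data frame with `time_index`, `accuracy`, `sem`.
#' @export
time_resolved_decode <- function(amplitudes, labels, folds,
                                 hp = default_hp(), seed = 1) {
  stopifnot(length(hp$hidden) == 0)
  n_t <- dim(amplitudes)[3]
  classes <- sort(unique(as.character(labels)))
  out <- lapply(seq_len(n_t), function(tt) {
    xt <- amplitudes[, , tt, drop = FALSE][, , 1, drop = FALSE]
    dim(xt) <- dim(amplitudes)[1:2]
    accs <- vapply(seq_along(folds), function(f) {
      fit <- train_classifier(xt[folds[[f]]$train, , drop = FALSE],
                              labels[folds[[f]]$train], hp = hp,
                              x_val = xt[folds[[f]]$validation, , drop = FALSE],
                              y_val = labels[folds[[f]]$validation],
                              classes = classes, seed = seed + f)
      pred <- predict(fit, xt[folds[[f]]$test, , drop = FALSE],
                      type = "class")
      mean(pred == labels[folds[[f]]$test])
    }, numeric(1))
    c(accuracy = mean(accs),
      sem = stats::sd(accs) / sqrt(length(accs)))
  })
  out <- do.call(rbind, out)
  data.frame(time_index = seq_len(n_t), accuracy = out[, "accuracy"],
             sem = out[, "sem"])
}

#' Accuracy scaling with training-set size
#'
#' Subsamples the training set class-by-class (so every class stays
#' present), retrains at each fraction, and fits an ordinary least-squares
#' line of test accuracy against the number of training examples. Validation
#' and test sets are untouched.
#'
#' @param x Features; `y` labels; `folds` a [make_folds()] object.
#' @param fractions Training-set fractions in `(0, 1]`.
#' @param hp Hyperparameters for every fit.
#' @param seed Integer seed.
#' @return List with `results` (data frame: fraction, n_train, accuracy,
#'   sem) and `slope_per_1000` (OLS slope of accuracy on training examples,
#'   per 1000 examples).
#' @export
scaling_experiment <- function(x, y, folds, fractions = c(0.5, 0.75, 1.0),
                               hp = default_hp(), seed = 1) {
  y <- as.character(y)
  classes <- sort(unique(y))
  rows <- lapply(fractions, function(fr) {
    accs <- vapply(seq_along(folds), function(f) {
      tr <- folds[[f]]$train
      if (fr < 1) {
        set.seed(seed + round(1000 * fr) + f)
        tr <- unlist(lapply(split(tr, y[tr]), function(idx) {
          k <- max(1L, round(fr * length(idx)))
          sample(idx, k)
        }), use.names = FALSE)
      }
      fit <- train_classifier(x[tr, , drop = FALSE], y[tr], hp = hp,
                              x_val = x[folds[[f]]$validation, , drop = FALSE],
                              y_val = y[folds[[f]]$validation],
                              classes = classes, seed = seed + f)
      pred <- predict(fit, x[folds[[f]]$test, , drop = FALSE], type = "class")
      mean(pred == y[folds[[f]]$test])
    }, numeric(1))
    n_train <- if (fr < 1) {
      mean(vapply(folds, function(fd) {
        sum(vapply(split(fd$train, y[fd$train]), function(idx) {
          max(1L, round(fr * length(idx)))
        }, numeric(1)))
      }, numeric(1)))
    } else mean(vapply(folds, function(fd) length(fd$train), numeric(1)))
    data.frame(fraction = fr, n_train = n_train, accuracy = mean(accs),
               sem = stats::sd(accs) / sqrt(length(accs)))
  })
  results <- do.call(rbind, rows)
  slope <- if (nrow(results) >= 2) {
    unname(stats::coef(stats::lm(accuracy ~ n_train, data = results))[2]) * 1000
  } else NA_real_
  list(results = results, slope_per_1000 = slope)
}

#' Decode from single bands and band + high-gamma concatenations
#'
#' For each candidate band: classify from the band's features alone, then
#' from the band's features concatenated with the high-gamma features. Both
#' accuracies are normalized to chance, and the concatenation's change from
#' the high-gamma baseline is reported against the baseline's
#' cross-validation standard deviation.
#'
#' @param band_features Named list of `[n x p_b]` feature matrices.
#' @param hg_features `[n x p]` high-gamma feature matrix (trial-aligned
#'   with every band).
#' @param labels Trial labels; `folds` a [make_folds()] object.
#' @param hp Hyperparameters for every fit.
#' @param seed Integer seed.
#' @return List with `baseline` (high-gamma accuracy, sd, chance) and
#'   `bands` (data frame: band, accuracy alone, accuracy concatenated,
#'   both /chance, delta vs baseline, baseline sd).
#' @export
band_comparison_experiment <- function(band_features, hg_features, labels,
                                       folds, hp = default_hp(), seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  stopifnot(all(vapply(band_features, nrow, numeric(1)) == nrow(hg_features)))

  fold_eval <- function(x) {
    vapply(seq_along(folds), function(f) {
      fit <- train_classifier(x[folds[[f]]$train, , drop = FALSE],
                              labels[folds[[f]]$train], hp = hp,
                              x_val = x[folds[[f]]$validation, , drop = FALSE],
                              y_val = labels[folds[[f]]$validation],
                              classes = classes, seed = seed + f)
      pred <- predict(fit, x[folds[[f]]$test, , drop = FALSE], type = "class")
      mean(pred == labels[folds[[f]]$test])
    }, numeric(1))
  }
  chance <- mean(vapply(seq_along(folds), function(f) {
    estimate_chance(labels[folds[[f]]$train], labels[folds[[f]]$test],
                    seed = seed + f)$chance
  }, numeric(1)))

  hg_acc <- fold_eval(hg_features)
  base <- list(accuracy = mean(hg_acc), sd = stats::sd(hg_acc),
               chance = chance)

  rows <- lapply(names(band_features), function(b) {
    alone <- fold_eval(band_features[[b]])
    concat <- fold_eval(cbind(band_features[[b]], hg_features))
    data.frame(band = b,
               accuracy_alone = mean(alone),
               accuracy_concat = mean(concat),
               alone_over_chance = mean(alone) / chance,
               concat_over_chance = mean(concat) / chance,
               delta_vs_hg = mean(concat) - base$accuracy,
               hg_sd = base$sd)
  })
  list(baseline = base, bands = do.call(rbind, rows))
}

#' Paired comparison of two models' per-fold accuracies
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-fold accuracy
#' differences, Bonferroni corrected.
#'
#' @param acc_a,acc_b Equal-length per-fold accuracy vectors.
#' @param n_corrections Bonferroni factor (default 4); the corrected p is
#'   capped at 1.
#' @param alpha Significance level for the flag (default 0.05).
#' @return List with `p_raw`, `p_corrected`, `significant`, `degenerate`
#'   (all differences zero).
#' @export
paired_model_test <- function(acc_a, acc_b, n_corrections = 4, alpha = 0.05) {
  stopifnot(length(acc_a) == length(acc_b))
  d <- acc_a - acc_b
  if (all(d == 0)) {
    return(list(p_raw = NA_real_, p_corrected = NA_real_,
                significant = FALSE, degenerate = TRUE))
  }
  p <- stats::wilcox.test(acc_a, acc_b, paired = TRUE, exact = TRUE)$p.value
  p_corr <- min(1, p * n_corrections)
  list(p_raw = p, p_corrected = p_corr, significant = p_corr < alpha,
       degenerate = FALSE)
}

#' Pool per-fold test predictions into one table
#'
#' Runs one classifier per fold (trained on that fold's training set with
#' early stopping on its validation set) and collects test-set predicted
#' probability vectors, predicted labels and true labels, pooled across
#' folds -- the substrate for confusion, capacity and hierarchy analyses.
#'
#' @param x Features; `y` labels; `folds` a [make_folds()] object.
#' @param hp Hyperparameters; `seed` integer seed.
#' @return List with `probabilities` (`[n_test x class]`), `predicted`,
#'   `true`, `fold`, and `fold_accuracy` (per-fold test accuracy).
#' @export
crossval_predictions <- function(x, y, folds, hp = default_hp(), seed = 1) {
  y <- as.character(y)
  classes <- sort(unique(y))
  probs <- list(); pred <- list(); truth <- list(); fold_id <- list()
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    fit <- train_classifier(x[folds[[f]]$train, , drop = FALSE],
                            y[folds[[f]]$train], hp = hp,
                            x_val = x[folds[[f]]$validation, , drop = FALSE],
                            y_val = y[folds[[f]]$validation],
                            classes = classes, seed = seed + f)
    p <- predict(fit, x[folds[[f]]$test, , drop = FALSE], type = "prob")
    probs[[f]] <- p
    pred[[f]] <- classes[max.col(p, ties.method = "first")]
    truth[[f]] <- y[folds[[f]]$test]
    fold_id[[f]] <- rep(f, nrow(p))
    fold_acc[f] <- mean(pred[[f]] == truth[[f]])
  }
  list(probabilities = do.call(rbind, probs),
       predicted = unlist(pred), true = unlist(truth),
       fold = unlist(fold_id), fold_accuracy = fold_acc)
}
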