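test_that("folds are stratified 80-10-10 with mutually exclusive test sets", {
  labels <- rep(paste0("c", 1:57), each = 10)
  folds <- make_folds(labels, n_folds = 10, seed = 1)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_identical(sort(all_test), seq_along(labels))   # union = all, no overlap
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$validation, f$test), 0)
    # every class appears in every test set at the minimum class size
    expect_setequal(unique(labels[f$test]), unique(labels))
    expect_equal(length(f$train) / length(labels), 0.8, tolerance = 0.01)
  }
})

test_that("classes below the minimum size are excluded from all folds", {
  labels <- c(rep("big", 40), rep("small", 9))
  folds <- make_folds(labels, n_folds = 5, seed = 2)
  expect_identical(attr(folds, "dropped_classes"), "small")
  used <- unlist(lapply(folds, function(f) c(f$train, f$validation, f$test)))
  expect_false(any(labels[unique(used)] == "small"))
  expect_error(make_folds(rep(c("a", "b"), each = 5)), "no class")
})

test_that("the chance estimator matches its closed-form expectation", {
  # uniform 57-class problem: chance ~ 1/57
  labels <- rep(paste0("c", 1:57), each = 20)
  ch <- estimate_chance(labels, labels, n_resamples = 200, seed = 1)
  se <- stats::sd(ch$resamples) / sqrt(length(ch$resamples))
  expect_lt(abs(ch$chance - 1 / 57), 2 * se + 1e-3)

  # single-class problem is certain
  expect_equal(estimate_chance(rep("a", 30), rep("a", 10))$chance, 1)

  # train p, test q: expectation sum(p * q)
  train <- rep(c("a", "b", "c"), c(50, 30, 20))
  test <- rep(c("a", "b", "c"), c(20, 30, 50))
  ch2 <- estimate_chance(train, test, n_resamples = 400, seed = 3)
  expect_lt(abs(ch2$chance - sum(c(.5, .3, .2) * c(.2, .3, .5))), 0.02)
})

test_that("softmax probabilities normalize and logistic training separates Gaussians", {
  g <- gaussian_dataset()
  folds <- make_folds(g$y, n_folds = 5, seed = 1)
  f1 <- folds[[1]]
  fit <- train_classifier(g$x[f1$train, ], g$y[f1$train], default_hp(),
                          g$x[f1$validation, ], g$y[f1$validation], seed = 2)
  p <- predict(fit, g$x[f1$test, ], type = "prob")
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  acc <- mean(predict(fit, g$x[f1$test, ], type = "class") == g$y[f1$test])
  expect_gte(acc, 0.95)
})

test_that("a zero-hidden-layer network agrees with an independent multinomial logistic fit", {
  g <- gaussian_dataset(n_per_class = 150, delta = 2.5, seed = 9)
  idx <- sample(seq_along(g$y))
  tr <- idx[1:200]; va <- idx[201:250]; te <- idx[251:300]
  fit <- train_classifier(g$x[tr, ], g$y[tr], default_hp(max_epochs = 150),
                          g$x[va, ], g$y[va], seed = 4)
  acc_ours <- mean(predict(fit, g$x[te, ], type = "class") == g$y[te])
  df <- data.frame(y = factor(g$y), x1 = g$x[, 1], x2 = g$x[, 2])
  ref <- nnet::multinom(y ~ x1 + x2, data = df[tr, ], trace = FALSE)
  acc_ref <- mean(predict(ref, df[te, ]) == df$y[te])
  expect_lt(abs(acc_ours - acc_ref), 0.011)
})

test_that("hidden layers solve XOR where the linear model cannot", {
  d <- xor_dataset()
  folds <- make_folds(d$cluster, n_folds = 5, seed = 1)   # cluster-stratified
  f1 <- folds[[1]]
  # the linear model is trained to its likelihood optimum (no accuracy-based
  # early stopping): on symmetric XOR that optimum carries no signal
  lin <- train_classifier(d$x[f1$train, ], d$y[f1$train],
                          default_hp(max_epochs = 100), seed = 1)
  deep <- train_classifier(d$x[f1$train, ], d$y[f1$train],
                           default_hp(hidden = 16, lr = 0.2, max_epochs = 200),
                           d$x[f1$validation, ], d$y[f1$validation], seed = 1)
  acc_lin <- mean(predict(lin, d$x[f1$test, ], type = "class") == d$y[f1$test])
  acc_deep <- mean(predict(deep, d$x[f1$test, ], type = "class") == d$y[f1$test])
  expect_lt(acc_lin, 0.7)
  expect_gte(acc_deep, 0.9)
})

test_that("training is deterministic under a fixed seed", {
  g <- gaussian_dataset(n_per_class = 60)
  fit1 <- train_classifier(g$x, g$y, default_hp(max_epochs = 10), seed = 5)
  fit2 <- train_classifier(g$x, g$y, default_hp(max_epochs = 10), seed = 5)
  expect_identical(fit1$w, fit2$w)
})

test_that("random search records every draw and avoids divergent settings", {
  g <- gaussian_dataset(n_per_class = 40, delta = 3, seed = 12)
  folds <- make_folds(g$y, n_folds = 4, seed = 1)

  # one draw trivially wins
  one <- random_search(g$x, g$y, folds, space = function() default_hp(),
                       n_draws = 1, seed = 2)
  expect_identical(one$best_index, 1L)

  # a known-good and a known-divergent setting: the divergent lr never wins
  toggle <- local({
    k <- 0
    function() {
      k <<- k + 1
      if (k %% 2 == 0) default_hp(lr = 1e3, max_epochs = 15) else
        default_hp(lr = 0.05, max_epochs = 15)
    }
  })
  res <- random_search(g$x, g$y, folds, space = toggle, n_draws = 6, seed = 3)
  expect_identical(res$best_index %% 2L, 1L)
  expect_identical(nrow(res$record), 6L)

  # seeded determinism of the winner
  r1 <- random_search(g$x, g$y, folds, space = default_search_space(
    max_epochs = 5), n_draws = 2, seed = 7)
  r2 <- random_search(g$x, g$y, folds, space = default_search_space(
    max_epochs = 5), n_draws = 2, seed = 7)
  expect_identical(r1$best_index, r2$best_index)
  expect_equal(r1$record, r2$record)
})

test_that("restricted tasks remap predictions and flag degenerate cases", {
  inv <- make_inventory()
  # consonant task: /bi/ for /ba/ is correct; vowel task: incorrect
  expect_equal(restricted_accuracy("bi", "ba", inv, "consonant")$accuracy, 1)
  expect_equal(restricted_accuracy("bi", "ba", inv, "vowel")$accuracy, 0)
  # predictions outside the location subset score 0 and flag degenerate
  res <- restricted_accuracy(c("ha", "ka"), c("ba", "da"), inv, "location")
  expect_equal(res$accuracy, 0)
  expect_true(res$degenerate)
  # trials whose truth is outside the task are dropped
  res2 <- restricted_accuracy(c("ba", "ka"), c("bi", "ha"), inv, "location")
  expect_identical(res2$n, 1L)
  expect_equal(res2$accuracy, 1)
  expect_error(restricted_accuracy("ba", "ha", inv, "location"), "no trial")
})

test_that("time-resolved decoding finds signal only where it was planted", {
  set.seed(31)
  n <- 240; n_t <- 6
  y <- rep(c("u", "v"), each = n / 2)
  amp <- array(stats::rnorm(n * 2 * n_t), dim = c(n, 2, n_t))
  # signal only at timepoints 4:6
  amp[y == "u", 1, 4:6] <- amp[y == "u", 1, 4:6] + 2.5
  folds <- make_folds(y, n_folds = 4, seed = 1)
  res <- time_resolved_decode(amp, y, folds, default_hp(max_epochs = 30),
                              seed = 2)
  expect_identical(nrow(res), 6L)
  expect_lt(mean(res$accuracy[1:3]), 0.65)   # ~ chance pre-onset
  expect_gt(mean(res$accuracy[4:6]), 0.85)
})

test_that("scaling experiment reproduces baseline at fraction 1 and OLS slopes", {
  g <- gaussian_dataset(n_per_class = 60, delta = 1.2, seed = 3)
  folds <- make_folds(g$y, n_folds = 4, seed = 2)
  res <- scaling_experiment(g$x, g$y, folds, fractions = c(0.5, 1),
                            hp = default_hp(max_epochs = 25), seed = 1)
  expect_identical(nrow(res$results), 2L)
  # two-point OLS slope equals delta-acc / delta-n
  d <- res$results
  manual <- (d$accuracy[2] - d$accuracy[1]) / (d$n_train[2] - d$n_train[1]) * 1000
  expect_equal(res$slope_per_1000, manual, tolerance = 1e-9)

  # exactly collinear points recover the planted line
  fake <- data.frame(n_train = c(100, 200, 300),
                     accuracy = 0.2 + 0.0005 * c(100, 200, 300))
  sl <- stats::coef(stats::lm(accuracy ~ n_train, fake))[2] * 1000
  expect_equal(unname(sl), 0.5)
})

test_that("paired fold comparison reproduces the exact signed-rank floor", {
  a <- seq(0.50, 0.59, by = 0.01)
  b <- a - seq(0.011, 0.020, by = 0.001)   # all positive, no tied ranks
  res <- paired_model_test(a, b, n_corrections = 4)
  expect_equal(res$p_corrected, 4 * 2 / 1024)
  expect_true(res$significant)
  res1 <- paired_model_test(a, b, n_corrections = 1)
  expect_equal(res1$p_raw, res1$p_corrected)
  deg <- paired_model_test(a, a)
  expect_true(deg$degenerate)
})
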