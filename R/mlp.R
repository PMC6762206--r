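#' Hyperparameters for the softmax classifier
#'
#' With `hidden = integer(0)` the model is exactly multinomial logistic
#' regression; with one or more hidden layers it is a fully connected
#' network trained by Nesterov momentum with an exponentially decaying
#' learning rate, a linearly increasing momentum fraction (from 0.5 to
#' `momentum_sat`), inverted dropout, weight decay, and per-unit max-norm
#' clipping of incoming weights. Training early-stops when validation
#' accuracy has not improved for `patience` epochs.
#'
#' @param hidden Integer vector of hidden-layer widths (empty = logistic
#'   regression).
#' @param activation `"tanh"` or `"relu"`.
#' @param lr Initial learning rate.
#' @param lr_decay Per-epoch multiplicative decay of the learning rate.
#' @param lr_floor Learning-rate floor.
#' @param momentum_sat Momentum saturation value (initial fraction is 0.5).
#' @param momentum_ramp Epochs over which momentum ramps linearly to
#'   saturation.
#' @param dropout Hidden-unit dropout probability (activations are rescaled
#'   by `1 / (1 - dropout)` during training).
#' @param weight_decay L2 penalty coefficient.
#' @param max_norm Maximum L2 norm of any unit's incoming weight vector.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience, epochs.
#' @return A list of class `hp`.
#' @export
default_hp <- function(hidden = integer(0), activation = c("tanh", "relu"),
                       lr = 0.1, lr_decay = 0.99, lr_floor = 1e-6,
                       momentum_sat = 0.95, momentum_ramp = 10,
                       dropout = 0, weight_decay = 0, max_norm = Inf,
                       batch_size = 64, max_epochs = 100, patience = 10) {
  activation <- match.arg(activation)
  stopifnot(lr > 0, dropout >= 0, dropout < 1, weight_decay >= 0,
            max_norm > 0, batch_size >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), activation = activation,
                 lr = lr, lr_decay = lr_decay, lr_floor = lr_floor,
                 momentum_sat = momentum_sat, momentum_ramp = momentum_ramp,
                 dropout = dropout, weight_decay = weight_decay,
                 max_norm = max_norm, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "hp")
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)          # max subtraction for stability
  e <- exp(z)
  e / rowSums(e)
}

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a) (a > 0) * 1))
}

clip_max_norm <- function(w, max_norm) {
  if (!is.finite(max_norm)) return(w)
  nrm <- sqrt(colSums(w^2))
  scale <- pmin(1, max_norm / pmax(nrm, 1e-12))
  sweep(w, 2, scale, `*`)
}

#' Train a softmax classifier (multinomial logistic or deep network)
#'
#' Minimizes the multiclass negative log-likelihood of a softmax output
#' layer over the training set. Zero hidden layers reduces the model exactly
#' to multinomial logistic regression. Training is deterministic under a
#' fixed seed. If a validation set is supplied, the parameters with the best
#' validation accuracy are kept and training stops after `hp$patience`
#' epochs without improvement.
#'
#' @param x `[n x p]` feature matrix (trials x rasterized features).
#' @param y Label vector, length `n`.
#' @param hp A [default_hp()] object.
#' @param x_val,y_val Optional validation set for early stopping.
#' @param classes Class levels fixing the output order (default: sorted
#'   unique training labels).
#' @param seed Integer seed for initialization, batching and dropout.
#' @return A `softmax_classifier` with elements `w`, `b` (per-layer
#'   parameters), `classes`, `hp`, `epochs_run`, `validation_accuracy`.
#' @seealso [predict.softmax_classifier()]
#' @export
train_classifier <- function(x, y, hp = default_hp(), x_val = NULL,
                             y_val = NULL, classes = NULL, seed = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  if (anyNA(yi)) stop("labels outside `classes`")
  n <- nrow(x)
  n_class <- length(classes)
  sizes <- c(ncol(x), hp$hidden, n_class)
  act <- act_fun(hp$activation)
  n_layers <- length(sizes) - 1L

  set.seed(seed)
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  vw <- vector("list", n_layers)
  vb <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    sc <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    w[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sc),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
    vw[[l]] <- w[[l]] * 0
    vb[[l]] <- b[[l]] * 0
  }

  y_onehot <- matrix(0, n, n_class)
  y_onehot[cbind(seq_len(n), yi)] <- 1

  forward <- function(w, b, x, training = FALSE) {
    a <- list(x)        # post-dropout activations (inputs to each layer)
    pre <- list()       # pre-dropout activations (for the derivative)
    masks <- list()
    h <- x
    if (n_layers > 1) {
      for (l in seq_len(n_layers - 1)) {
        h <- act$f(sweep(h %*% w[[l]], 2, b[[l]], `+`))
        pre[[l]] <- h
        if (training && hp$dropout > 0) {
          m <- matrix(stats::rbinom(length(h), 1, 1 - hp$dropout),
                      nrow(h)) / (1 - hp$dropout)
          h <- h * m
          masks[[l]] <- m
        }
        a[[l + 1]] <- h
      }
    }
    logits <- sweep(h %*% w[[n_layers]], 2, b[[n_layers]], `+`)
    list(a = a, pre = pre, masks = masks, p = softmax(logits))
  }

  evaluate_acc <- function(w, b, x, yi) {
    p <- forward(w, b, x)$p
    mean(max.col(p, ties.method = "first") == yi)
  }

  yvi <- NULL
  if (!is.null(x_val)) {
    x_val <- as.matrix(x_val)
    yvi <- match(as.character(y_val), classes)
  }

  best <- list(w = w, b = b, acc = -Inf, epoch = 0L)
  stall <- 0L
  epoch <- 0L
  while (epoch < hp$max_epochs) {
    epoch <- epoch + 1L
    lr <- max(hp$lr * hp$lr_decay^(epoch - 1), hp$lr_floor)
    mu <- min(hp$momentum_sat,
              0.5 + (hp$momentum_sat - 0.5) * (epoch - 1) / hp$momentum_ramp)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
    for (idx in batches) {
      xb <- x[idx, , drop = FALSE]
      yb <- y_onehot[idx, , drop = FALSE]
      # Nesterov: gradient at the lookahead point theta + mu * v
      wl <- Map(function(wi, vi) wi + mu * vi, w, vw)
      bl <- Map(function(bi, vi) bi + mu * vi, b, vb)
      fw <- forward(wl, bl, xb, training = TRUE)
      delta <- (fw$p - yb) / nrow(xb)
      for (l in rev(seq_len(n_layers))) {
        gw <- crossprod(fw$a[[l]], delta) + hp$weight_decay * wl[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(wl[[l]])
          if (hp$dropout > 0 && length(fw$masks) >= l - 1 &&
              !is.null(fw$masks[[l - 1]])) {
            delta <- delta * fw$masks[[l - 1]]
          }
          delta <- delta * act$df(fw$pre[[l - 1]])
        }
        vw[[l]] <- mu * vw[[l]] - lr * gw
        vb[[l]] <- mu * vb[[l]] - lr * gb
        w[[l]] <- clip_max_norm(w[[l]] + vw[[l]], hp$max_norm)
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    if (!is.null(yvi)) {
      acc <- evaluate_acc(w, b, x_val, yvi)
      if (acc > best$acc + 1e-12) {
        best <- list(w = w, b = b, acc = acc, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hp$patience) break
      }
    }
  }
  if (is.null(yvi)) best <- list(w = w, b = b, acc = NA_real_, epoch = epoch)

  structure(list(w = best$w, b = best$b, classes = classes, hp = hp,
                 activation = hp$activation, epochs_run = epoch,
                 validation_accuracy = best$acc),
            class = "softmax_classifier")
}

#' Predict class probabilities or labels
#'
#' Every returned probability vector is non-negative and sums to 1.
#'
#' @param object A [train_classifier()] fit.
#' @param newdata `[n x p]` feature matrix.
#' @param type `"prob"` for the `[n x class]` softmax probability matrix,
#'   `"class"` for thresholded labels.
#' @param ... Unused.
#' @export
predict.softmax_classifier <- function(object, newdata,
                                       type = c("prob", "class"), ...) {
  type <- match.arg(type)
  h <- as.matrix(newdata)
  act <- act_fun(object$activation)
  n_layers <- length(object$w)
  if (n_layers > 1) {
    for (l in seq_len(n_layers - 1)) {
      h <- act$f(sweep(h %*% object$w[[l]], 2, object$b[[l]], `+`))
    }
  }
  p <- softmax(sweep(h %*% object$w[[n_layers]], 2, object$b[[n_layers]], `+`))
  colnames(p) <- object$classes
  if (type == "prob") p else
    object$classes[max.col(p, ties.method = "first")]
}
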