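#' Feed-forward network specification
#'
#' Architecture and training settings for the small fully connected
#' regression networks used by the pipeline: ReLU hidden layers, a linear
#' output unit, mean-squared-error loss, mini-batch Adam, and early stopping
#' on a held-out validation fraction with best-weight restoration.
#'
#' @param input_dim Number of input features.
#' @param hidden_nodes Integer vector of hidden-layer widths (default three
#'   layers of 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param beta1,beta2,epsilon Adam moment-decay and stabilisation constants
#'   (defaults 0.9, 0.999, 1e-8).
#' @param batch_size Mini-batch size for the Adam updates (default 16); the
#'   training rows are reshuffled every epoch with the seeded generator.
#' @param max_epochs Maximum training epochs (default 2000).
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without a validation-loss improvement (default 50).
#' @param val_fraction Fraction of the training rows held out for validation
#'   (default 0.1).
#' @param standardize Standardise inputs by training-set mean/SD (default
#'   `TRUE`). Targets are always standardised internally and predictions
#'   returned on the original scale.
#' @param seed Integer seed controlling weight initialisation and the
#'   validation split.
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden_nodes = c(128, 128, 128),
                     learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     epsilon = 1e-8, batch_size = 16, max_epochs = 2000,
                     patience = 50, val_fraction = 0.1, standardize = TRUE,
                     seed = 1L) {
  stopifnot(input_dim >= 1, all(hidden_nodes >= 1), learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1,
            patience < max_epochs, val_fraction > 0, val_fraction < 0.5)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_nodes = as.integer(hidden_nodes),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Specification of the whole-body-index estimation network
#'
#' Three ReLU hidden layers of 128 nodes; input dimension 5-7 depending on
#' the feature set variant.
#' @param input_dim Input features (default 7, the full variant).
#' @param seed Seed.
#' @param ... Passed to [mlp_spec()].
#' @return An `mlp_spec`.
#' @export
network1_spec <- function(input_dim = 7, seed = 1L, ...) {
  mlp_spec(input_dim, hidden_nodes = c(128, 128, 128), seed = seed, ...)
}

#' Specification of the percent-body-fat estimation network
#'
#' Three ReLU hidden layers of 256 nodes; input dimension 5 or 8 depending
#' on whether lower-body circumferences are included.
#' @param input_dim Input features (default 8, with circumferences).
#' @param seed Seed.
#' @param ... Passed to [mlp_spec()].
#' @return An `mlp_spec`.
#' @export
network2_spec <- function(input_dim = 8, seed = 1L, ...) {
  mlp_spec(input_dim, hidden_nodes = c(256, 256, 256), seed = seed, ...)
}

relu <- function(x) x * (x > 0)

mlp_forward <- function(W, b, X) {
  acts <- vector("list", length(W))
  A <- X
  for (l in seq_along(W)) {
    Z <- A %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], "+")
    A <- if (l < length(W)) relu(Z) else Z
    acts[[l]] <- A
  }
  acts
}

#' Train a feed-forward regression network
#'
#' Mini-batch Adam on the mean-squared error, with the last
#' `val_fraction` of a seeded shuffle held out for validation. Training
#' stops when the validation loss has not improved for `patience` epochs (or
#' at `max_epochs`), and the weights from the best validation epoch are
#' restored. The same spec, data and seed always produce identical weights.
#'
#' @param spec An [mlp_spec()].
#' @param features Numeric matrix, `spec$input_dim` columns.
#' @param targets Numeric response vector.
#' @return Object of class `mlp_model`: `spec`, `weights`/`biases` (lists of
#'   matrices/vectors), standardisation constants (`x_center`, `x_scale`,
#'   `y_center`, `y_scale`), `feature_names`, `history` (data.frame of
#'   epoch/train/validation loss) and `stopped_epoch`.
#' @export
train_mlp <- function(spec, features, targets) {
  stopifnot(inherits(spec, "mlp_spec"))
  X <- as.matrix(features)
  y <- as.numeric(targets)
  if (ncol(X) != spec$input_dim) {
    stop(sprintf("train_mlp: feature dim %d != spec input_dim %d",
                 ncol(X), spec$input_dim), call. = FALSE)
  }
  n <- nrow(X)
  if (n < 20) stop("train_mlp: need at least 20 training rows", call. = FALSE)
  if (length(y) != n) stop("train_mlp: targets length mismatch", call. = FALSE)

  set.seed(spec$seed)

  # standardisation constants (inputs optional, targets always)
  if (spec$standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
  } else {
    x_center <- rep(0, ncol(X)); x_scale <- rep(1, ncol(X))
  }
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  # seeded validation split
  idx <- sample.int(n)
  n_val <- max(1L, round(spec$val_fraction * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
  Xva <- Xs[val_idx, , drop = FALSE]; yva <- ys[val_idx]
  ntr <- length(tr_idx)

  # He-initialised layers
  dims <- c(spec$input_dim, spec$hidden_nodes, 1L)
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  mW <- vector("list", L); vW <- vector("list", L)
  mb <- vector("list", L); vb <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
    mW[[l]] <- matrix(0, dims[l], dims[l + 1]); vW[[l]] <- mW[[l]]
    mb[[l]] <- rep(0, dims[l + 1]); vb[[l]] <- mb[[l]]
  }

  best_val <- Inf; best_W <- W; best_b <- b; best_epoch <- 0L
  since_best <- 0L
  hist_epoch <- integer(0); hist_tr <- numeric(0); hist_va <- numeric(0)
  lr <- spec$learning_rate; b1 <- spec$beta1; b2 <- spec$beta2
  eps <- spec$epsilon
  step <- 0L

  batches_of <- function(ord) {
    split(ord, ceiling(seq_along(ord) / spec$batch_size))
  }

  for (epoch in seq_len(spec$max_epochs)) {
    losses <- numeric(0)
    for (batch in batches_of(sample.int(ntr))) {
      Xb <- Xtr[batch, , drop = FALSE]
      yb <- ytr[batch]
      nb <- length(batch)
      acts <- mlp_forward(W, b, Xb)
      err <- acts[[L]][, 1] - yb
      losses <- c(losses, sum(err^2))
      if (!all(is.finite(err))) {
        stop(sprintf("train_mlp: non-finite loss at epoch %d (diverged)",
                     epoch), call. = FALSE)
      }

      # backward pass
      delta <- matrix(2 * err / nb, ncol = 1)       # dL/dZ_out
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in L:1) {
        A_prev <- if (l == 1) Xb else acts[[l - 1]]
        gW[[l]] <- crossprod(A_prev, delta)
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (acts[[l - 1]] > 0)
        }
      }

      # Adam update
      step <- step + 1L
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }
    train_loss <- sum(losses) / ntr

    val_acts <- mlp_forward(W, b, Xva)
    val_loss <- mean((val_acts[[L]][, 1] - yva)^2)
    hist_epoch <- c(hist_epoch, epoch)
    hist_tr <- c(hist_tr, train_loss)
    hist_va <- c(hist_va, val_loss)

    if (val_loss < best_val) {
      best_val <- val_loss; best_W <- W; best_b <- b
      best_epoch <- epoch; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= spec$patience) break
    }
  }

  structure(list(spec = spec, weights = best_W, biases = best_b,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 feature_names = colnames(X),
                 history = data.frame(epoch = hist_epoch,
                                      train_loss = hist_tr,
                                      val_loss = hist_va),
                 stopped_epoch = length(hist_epoch),
                 best_epoch = best_epoch),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%s-1, stopped at epoch %d (best %d, val MSE %.4g)\n",
              x$spec$input_dim,
              paste(x$spec$hidden_nodes, collapse = "-"),
              x$stopped_epoch, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Predict with a trained feed-forward network
#'
#' Deterministic forward pass applying the stored input standardisation and
#' returning predictions on the original target scale. Batch prediction
#' equals row-by-row prediction.
#'
#' @param model An `mlp_model`.
#' @param features Numeric matrix (rows = subjects) or vector (one subject)
#'   with `input_dim` columns; if column names are present they must match
#'   the training features (any order).
#' @return Numeric vector of predictions.
#' @export
predict_mlp <- function(model, features) {
  stopifnot(inherits(model, "mlp_model"))
  if (!is.matrix(features) && !is.data.frame(features)) {
    features <- matrix(features, nrow = 1)
  }
  X <- as.matrix(features)
  if (ncol(X) != model$spec$input_dim) {
    stop("predict_mlp: feature dimension mismatch", call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(model$feature_names) &&
      !identical(colnames(X), model$feature_names)) {
    if (!setequal(colnames(X), model$feature_names)) {
      stop("predict_mlp: feature names do not match model", call. = FALSE)
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  acts <- mlp_forward(model$weights, model$biases, Xs)
  acts[[length(acts)]][, 1] * model$y_scale + model$y_center
}
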