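#' Sub-model configuration
#'
#' Hyperparameters of one fully connected sub-network. Defaults follow the
#' ensemble's reference architecture: hidden layers of 64, 128, 256, 128
#' and 64 ReLU units, a 2-unit sigmoid output (one unit per class; the
#' positive unit's activation is the score), and dropout 0.3 applied before
#' the output layer. Training uses Adam with binary cross-entropy, a 10%
#' validation split and early stopping.
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param dropout_rate Dropout probability on the last hidden layer, in
#'   `[0, 1)`.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); the best weights are restored.
#' @param validation_fraction Fraction of the training rows held out for
#'   early stopping.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A list of class `submodel_config`.
#' @export
submodel_config <- function(hidden_layers = c(64L, 128L, 256L, 128L, 64L),
                            dropout_rate = 0.3,
                            epochs = 50L,
                            batch_size = 256L,
                            learning_rate = 1e-3,
                            patience = 5L,
                            validation_fraction = 0.1,
                            seed = 1L) {
  stopifnot(length(hidden_layers) >= 1L, all(hidden_layers >= 1L),
            dropout_rate >= 0, dropout_rate < 1,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "submodel_config")
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(dims) {
  # He-style initialisation, seeded by the caller's RNG state
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    sd <- sqrt(2 / dims[l])
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sd),
                     nrow = dims[l])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass; returns list of activations per layer (a[[1]] is the input).
mlp_forward <- function(par, X, dropout_rate = 0, drop_mask = NULL) {
  nl <- length(par$W)
  a <- vector("list", nl + 1L)
  a[[1]] <- X
  for (l in seq_len(nl)) {
    z <- sweep(a[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < nl) {
      a[[l + 1L]] <- relu(z)
      if (l == nl - 1L && dropout_rate > 0 && !is.null(drop_mask)) {
        # inverted dropout before the output layer
        a[[l + 1L]] <- a[[l + 1L]] * drop_mask / (1 - dropout_rate)
      }
    } else {
      a[[l + 1L]] <- sigmoid(z)
    }
  }
  a
}

# Mean binary cross-entropy over both output units.
bce_loss <- function(P, Tm) {
  eps <- 1e-12
  -mean(Tm * log(P + eps) + (1 - Tm) * log(1 - P + eps))
}

#' Train one sub-network
#'
#' Fits a fully connected ReLU network with a 2-unit sigmoid output on an
#' encoded feature matrix. Training is fully seeded (initialisation,
#' shuffling, dropout, validation split) and therefore reproducible on a
#' single CPU.
#'
#' @param features Numeric matrix, one row per sample (see
#'   [encode_batch()]).
#' @param labels 0/1 vector of length `nrow(features)`.
#' @param config A [submodel_config()].
#' @return An object of class `promethyl_mlp` exposing `predict(model, X)`,
#'   which returns the positive-unit probability per row.
#' @export
train_submodel <- function(features, labels, config = submodel_config()) {
  if (!is.matrix(features)) features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree: ", nrow(features), " rows vs ",
         length(labels), " labels")
  }
  if (anyNA(features) || any(!is.finite(features))) {
    stop("features contain NA or non-finite values")
  }
  if (length(unique(labels)) < 2L) {
    stop("training data contains a single class; both classes are required")
  }
  n <- nrow(features)
  dims <- c(ncol(features), config$hidden_layers, 2L)
  Tm_all <- cbind(1 - labels, labels)   # columns: negative unit, positive unit

  with_seed(config$seed, {
    par <- mlp_init(dims)
    # validation split for early stopping
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- features[tr_idx, , drop = FALSE]
    Ttr <- Tm_all[tr_idx, , drop = FALSE]
    Xval <- features[val_idx, , drop = FALSE]
    Tval <- Tm_all[val_idx, , drop = FALSE]

    nl <- length(par$W)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    best <- list(loss = Inf, par = par, epoch = 0L)
    stall <- 0L

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nrow(Xtr))]
        X <- Xtr[idx, , drop = FALSE]
        Tm <- Ttr[idx, , drop = FALSE]
        m <- nrow(X)
        drop_mask <- NULL
        if (config$dropout_rate > 0) {
          drop_mask <- matrix(runif(m * dims[nl]) >= config$dropout_rate,
                              nrow = m)
        }
        a <- mlp_forward(par, X, config$dropout_rate, drop_mask)
        # backprop: sigmoid + BCE gives delta = (p - t) at the output
        delta <- (a[[nl + 1L]] - Tm) / m
        gW <- vector("list", nl); gb <- vector("list", nl)
        for (l in nl:1) {
          gW[[l]] <- crossprod(a[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(par$W[[l]])) * (a[[l]] > 0)
            if (l - 1L == nl - 1L && !is.null(drop_mask)) {
              delta <- delta * drop_mask / (1 - config$dropout_rate)
            }
          }
        }
        t_step <- t_step + 1
        lr_t <- config$learning_rate *
          sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
        for (l in seq_len(nl)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          par$W[[l]] <- par$W[[l]] - lr_t * mW[[l]] / (sqrt(vW[[l]]) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          par$b[[l]] <- par$b[[l]] - lr_t * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      aval <- mlp_forward(par, Xval)
      vloss <- bce_loss(aval[[nl + 1L]], Tval)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, par = par, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    structure(list(par = best$par, dims = dims, config = config,
                   val_loss = best$loss, best_epoch = best$epoch),
              class = "promethyl_mlp")
  })
}

#' @export
predict.promethyl_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$dims[1]) {
    stop("feature width ", ncol(X), " does not match the model's input width ",
         object$dims[1])
  }
  a <- mlp_forward(object$par, X)
  unname(a[[length(a)]][, 2])
}

#' @export
print.promethyl_mlp <- function(x, ...) {
  cat("Fully connected sub-network:",
      paste(x$dims, collapse = "-"),
      sprintf("(best epoch %d, validation loss %.4f)\n",
              x$best_epoch, x$val_loss))
  invisible(x)
}
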