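# Deep neural network classifier ----------------------------------------------
#
# A four-layer feed-forward network (input, two hidden layers, two-unit
# softmax output) in plain matrix code. Both hidden layers have the same
# width as the input feature vector; the first uses SELU, the second ReLU;
# inverted dropout is applied after each hidden activation during training;
# the network is trained with Adam on cross-entropy, with early stopping on
# validation loss.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
relu <- function(x) pmax(x, 0)
relu_grad <- function(x) (x > 0) * 1

act_fun <- function(name) switch(name, selu = selu, relu = relu,
                                 abort(sprintf("unknown activation '%s'", name)))
act_grad <- function(name) switch(name, selu = selu_grad, relu = relu_grad)

#' DNN hyperparameter configuration
#'
#' Architecture follows the fixed policy: two hidden layers whose widths
#' equal the input width, SELU then ReLU activations (the order is
#' switchable), 50% dropout after each hidden layer, and a two-unit softmax
#' output. Optimization settings are ordinary Adam defaults.
#'
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.5).
#' @param activations Hidden-layer activations, first then second (default
#'   `c("selu", "relu")`).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (default 10).
#' @param seed Integer seed for weight initialization, shuffling and dropout.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(dropout_rate = 0.5, activations = c("selu", "relu"),
                       learning_rate = 1e-3, batch_size = 128,
                       max_epochs = 100, patience = 10, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1)")
  }
  stopifnot(length(activations) == 2)
  structure(list(dropout_rate = dropout_rate, activations = activations,
                 learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed)),
            class = "dnn_config")
}

#' Build an untrained DNN
#'
#' Layer widths are `[input_width, input_width, input_width, 2]`. Weights
#' are initialized from a normal distribution scaled by the inverse square
#' root of the fan-in (the scaling under which SELU activations
#' self-normalize).
#'
#' @param input_width Number of input features (>= 1).
#' @param config A [dnn_config()].
#' @return A `gero_dnn` object.
#' @export
build_dnn <- function(input_width, config = dnn_config()) {
  if (input_width < 1) abort("`input_width` must be >= 1")
  w <- as.integer(input_width)
  withr::with_seed(config$seed, {
    init <- function(nin, nout) {
      matrix(rnorm(nin * nout, sd = 1 / sqrt(nin)), nrow = nin)
    }
    net <- list(
      W1 = init(w, w), b1 = numeric(w),
      W2 = init(w, w), b2 = numeric(w),
      W3 = init(w, 2), b3 = numeric(2),
      input_width = w, config = config, trained = FALSE, history = NULL
    )
  })
  structure(net, class = "gero_dnn")
}

#' Number of trainable parameters of a DNN
#'
#' @param net A `gero_dnn`.
#' @return Integer parameter count.
#' @export
dnn_n_params <- function(net) {
  length(net$W1) + length(net$b1) + length(net$W2) + length(net$b2) +
    length(net$W3) + length(net$b3)
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# Forward pass; dropout masks are drawn from the current RNG stream when
# `dropout = TRUE` (training), and omitted at inference.
dnn_forward <- function(net, x, dropout = FALSE) {
  cfg <- net$config
  if (!is.null(net$x_center)) {
    x <- sweep(sweep(x, 2, net$x_center), 2, net$x_scale, `/`)
  }
  f1 <- act_fun(cfg$activations[1]); f2 <- act_fun(cfg$activations[2])
  keep <- 1 - cfg$dropout_rate
  z1 <- sweep(x %*% net$W1, 2, net$b1, `+`)
  a1 <- f1(z1)
  m1 <- NULL
  if (dropout && cfg$dropout_rate > 0) {
    m1 <- matrix(runif(length(a1)) < keep, nrow = nrow(a1)) / keep
    a1 <- a1 * m1
  }
  z2 <- sweep(a1 %*% net$W2, 2, net$b2, `+`)
  a2 <- f2(z2)
  m2 <- NULL
  if (dropout && cfg$dropout_rate > 0) {
    m2 <- matrix(runif(length(a2)) < keep, nrow = nrow(a2)) / keep
    a2 <- a2 * m2
  }
  z3 <- sweep(a2 %*% net$W3, 2, net$b3, `+`)
  list(p = softmax_rows(z3), x = x, z1 = z1, a1 = a1, m1 = m1,
       z2 = z2, a2 = a2, m2 = m2)
}

cross_entropy <- function(p, y) {
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
}

dnn_gradients <- function(net, fwd, y) {
  cfg <- net$config
  g1 <- act_grad(cfg$activations[1]); g2 <- act_grad(cfg$activations[2])
  n <- length(y)
  yh <- matrix(0, n, 2); yh[cbind(seq_len(n), y + 1L)] <- 1
  dz3 <- (fwd$p - yh) / n
  dW3 <- crossprod(fwd$a2, dz3); db3 <- colSums(dz3)
  da2 <- tcrossprod(dz3, net$W3)
  if (!is.null(fwd$m2)) da2 <- da2 * fwd$m2
  dz2 <- da2 * g2(fwd$z2)
  dW2 <- crossprod(fwd$a1, dz2); db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, net$W2)
  if (!is.null(fwd$m1)) da1 <- da1 * fwd$m1
  dz1 <- da1 * g1(fwd$z1)
  dW1 <- crossprod(fwd$x, dz1); db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train a DNN with early stopping
#'
#' Minimizes cross-entropy with Adam over shuffled minibatches. When a
#' validation set is given, validation loss is monitored each epoch and the
#' best-epoch weights are restored after `patience` epochs without
#' improvement; otherwise training loss is monitored.
#'
#' @param net A `gero_dnn` from [build_dnn()].
#' @param x,y Training features (matrix) and 0/1 targets.
#' @param x_val,y_val Optional validation split for early stopping.
#' @return The trained `gero_dnn`, with a `history` tibble (epoch, train
#'   loss, monitored loss) and `epochs_run` / `best_epoch` fields.
#' @export
fit_dnn <- function(net, x, y, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(net, "gero_dnn"))
  if (ncol(x) != net$input_width) {
    abort(sprintf("input width mismatch: expected %d, got %d",
                  net$input_width, ncol(x)))
  }
  cfg <- net$config
  # standardize inputs on training statistics (stored with the network);
  # SELU self-normalization assumes roughly unit-scale inputs
  net$x_center <- colMeans(x)
  net$x_scale <- pmax(apply(x, 2, stats::sd), 1e-6)
  pars <- c("W1", "b1", "W2", "b2", "W3", "b3")
  m <- v <- lapply(net[pars], function(p) p * 0)
  names(m) <- names(v) <- pars
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  best <- net[pars]; best_loss <- Inf; best_epoch <- 0; stall <- 0
  history <- list()

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample(nrow(x))
      starts <- seq(1, length(idx), by = cfg$batch_size)
      for (s in starts) {
        b <- idx[s:min(s + cfg$batch_size - 1, length(idx))]
        fwd <- dnn_forward(net, x[b, , drop = FALSE], dropout = TRUE)
        gr <- dnn_gradients(net, fwd, y[b])
        t <- t + 1
        for (p in pars) {
          m[[p]] <- beta1 * m[[p]] + (1 - beta1) * gr[[p]]
          v[[p]] <- beta2 * v[[p]] + (1 - beta2) * gr[[p]]^2
          mhat <- m[[p]] / (1 - beta1^t)
          vhat <- v[[p]] / (1 - beta2^t)
          net[[p]] <- net[[p]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      train_loss <- cross_entropy(dnn_forward(net, x)$p, y)
      monitored <- if (!is.null(x_val)) {
        cross_entropy(dnn_forward(net, x_val)$p, y_val)
      } else {
        train_loss
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss,
                                 monitored_loss = monitored)
      if (monitored < best_loss - 1e-6) {
        best_loss <- monitored; best <- net[pars]
        best_epoch <- epoch; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= cfg$patience) break
      }
    }
  })
  net[pars] <- best
  net$trained <- TRUE
  net$history <- bind_rows(history)
  net$best_epoch <- best_epoch
  net$epochs_run <- nrow(net$history)
  net
}

#' @export
print.gero_dnn <- function(x, ...) {
  cat("<gero_dnn> layers [", x$input_width, ", ", x$input_width, ", ",
      x$input_width, ", 2]; ", dnn_n_params(x), " parameters; ",
      if (x$trained) paste0("trained (", x$epochs_run, " epochs, best ",
                            x$best_epoch, ")") else "untrained",
      "\n", sep = "")
  invisible(x)
}
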