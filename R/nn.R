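#' Specify one network layer
#'
#' @param width Number of units (>= 1).
#' @param activation Activation tag: `"sigmoid"`, `"tanh"`, or `"linear"`.
#' @param dropout_rate Dropout probability in \[0, 1) applied to this layer's
#'   output during training only.
#' @return A list of class `LayerSpec`.
#' @export
layer_spec <- function(width, activation = c("sigmoid", "tanh", "linear"),
                       dropout_rate = 0) {
  activation <- match.arg(activation)
  width <- as.integer(width)
  if (width < 1L) stop("layer width must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)")
  }
  structure(list(width = width, activation = activation,
                 dropout_rate = dropout_rate),
            class = "LayerSpec")
}

activation_fun <- function(z, tag) {
  switch(tag,
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         linear = z,
         stop(sprintf("unknown activation tag '%s'", tag)))
}

# Derivative expressed through the activation value a = f(z).
activation_deriv <- function(a, tag) {
  switch(tag,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         linear = array(1, dim = dim(a) %||% length(a)),
         stop(sprintf("unknown activation tag '%s'", tag)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize network parameters
#'
#' Weights are drawn from a seeded uniform Glorot distribution
#' (`limit = sqrt(6 / (fan_in + fan_out))`); biases start at zero. The
#' bottleneck index points at the narrowest layer (first one on ties).
#'
#' @param input_dim Input dimension (number of genes).
#' @param layers List of [layer_spec()] objects, input side first.
#' @param seed Integer seed for the weight draw.
#' @return A list of class `NetworkParams` with elements `layers` (each a
#'   list with `W`, `b`, `activation`, `dropout_rate`) and `bottleneck_index`.
#' @export
init_network <- function(input_dim, layers, seed = 1L) {
  if (length(layers) < 1L) stop("need at least one layer")
  set.seed(as.integer(seed))
  d <- as.integer(input_dim)
  params <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    p <- layers[[l]]$width
    limit <- sqrt(6 / (d + p))
    params[[l]] <- list(
      W = matrix(stats::runif(p * d, -limit, limit), nrow = p, ncol = d),
      b = numeric(p),
      activation = layers[[l]]$activation,
      dropout_rate = layers[[l]]$dropout_rate
    )
    d <- p
  }
  widths <- vapply(layers, `[[`, integer(1), "width")
  structure(list(layers = params,
                 input_dim = as.integer(input_dim),
                 bottleneck_index = which.min(widths)),
            class = "NetworkParams")
}

check_network <- function(params) {
  if (!inherits(params, "NetworkParams")) stop("`params` must be NetworkParams")
  d <- params$input_dim
  for (l in seq_along(params$layers)) {
    W <- params$layers[[l]]$W
    if (ncol(W) != d) {
      stop(sprintf("layer %d expects input of size %d, got %d", l, ncol(W), d))
    }
    d <- nrow(W)
  }
  invisible(TRUE)
}

#' Forward pass through a network
#'
#' Runs in inference mode (dropout disabled) and returns all intermediate
#' activations, as needed by the attribution engine. Input columns are
#' samples; a plain vector is treated as a single sample.
#'
#' @param params A `NetworkParams` object.
#' @param x Numeric vector (one sample) or matrix (`input_dim` x samples).
#' @param n_layers Number of leading layers to run (defaults to all; the
#'   encoder sub-network is `n_layers = params$bottleneck_index`).
#' @param keep_preactivations If `TRUE`, also return the pre-activation
#'   values `z = W a + b` of every layer.
#' @return A list with `activations` (list of per-layer outputs, same shape
#'   convention as `x`) and, optionally, `preactivations`.
#' @export
nn_forward <- function(params, x, n_layers = length(params$layers),
                       keep_preactivations = FALSE) {
  check_network(params)
  vec_in <- is.null(dim(x))
  a <- if (vec_in) matrix(x, ncol = 1L) else x
  if (nrow(a) != params$input_dim) {
    stop(sprintf("input has %d rows but the network expects %d",
                 nrow(a), params$input_dim))
  }
  acts <- vector("list", n_layers)
  pres <- if (keep_preactivations) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    layer <- params$layers[[l]]
    z <- layer$W %*% a + layer$b
    a <- activation_fun(z, layer$activation)
    if (keep_preactivations) pres[[l]] <- z
    acts[[l]] <- a
  }
  if (vec_in) {
    acts <- lapply(acts, drop)
    if (keep_preactivations) pres <- lapply(pres, drop)
  }
  out <- list(activations = acts)
  if (keep_preactivations) out$preactivations <- pres
  out
}

# Core minibatch trainer: Adam, optional inverted dropout on hidden layers,
# MAE or MSE data loss plus an L2 penalty on the weight matrices.
# Returns the updated params and the per-epoch mean batch loss.
nn_train <- function(params, X, Y, loss = c("mae", "mse"), epochs,
                     batch_size = 256L, l2_alpha = 0,
                     learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     adam_eps = 1e-8, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  check_network(params)
  m <- ncol(X)
  L <- length(params$layers)
  n_out <- nrow(params$layers[[L]]$W)
  if (nrow(Y) != n_out || ncol(Y) != m) stop("target dimensions do not match")
  set.seed(as.integer(seed))
  mW <- lapply(params$layers, function(l) l$W * 0)
  vW <- mW
  mb <- lapply(params$layers, function(l) l$b * 0)
  vb <- mb
  t_step <- 0L
  history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(m)
    starts <- seq(1L, m, by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, m)]
      bs <- length(idx)
      a <- X[, idx, drop = FALSE]
      acts <- vector("list", L)     # post-dropout (next layer's input)
      raw <- vector("list", L)      # pre-dropout activation values
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        layer <- params$layers[[l]]
        z <- layer$W %*% a + layer$b
        a_raw <- activation_fun(z, layer$activation)
        raw[[l]] <- a_raw
        if (layer$dropout_rate > 0 && l < L) {
          keep <- 1 - layer$dropout_rate
          mask <- matrix(stats::rbinom(length(a_raw), 1L, keep) / keep,
                         nrow = nrow(a_raw))
          masks[[l]] <- mask
          a <- a_raw * mask
        } else {
          a <- a_raw
        }
        acts[[l]] <- a
      }
      resid <- acts[[L]] - Y[, idx, drop = FALSE]
      data_loss <- if (loss == "mae") mean(abs(resid)) else mean(resid^2)
      pen <- if (l2_alpha > 0) {
        l2_alpha * sum(vapply(params$layers,
                              function(l) sum(l$W^2), numeric(1)))
      } else 0
      batch_loss <- data_loss + pen
      if (!is.finite(batch_loss)) {
        stop(sprintf("non-finite loss (%g) at epoch %d: aborting training",
                     batch_loss, epoch))
      }
      epoch_loss <- epoch_loss + batch_loss * bs
      grad_a <- if (loss == "mae") {
        sign(resid) / (n_out * bs)
      } else {
        2 * resid / (n_out * bs)
      }
      t_step <- t_step + 1L
      for (l in rev(seq_len(L))) {
        layer <- params$layers[[l]]
        if (!is.null(masks[[l]])) grad_a <- grad_a * masks[[l]]
        grad_z <- grad_a * activation_deriv(raw[[l]], layer$activation)
        a_prev <- if (l == 1L) X[, idx, drop = FALSE] else acts[[l - 1L]]
        gW <- grad_z %*% t(a_prev) + 2 * l2_alpha * layer$W
        gb <- rowSums(grad_z)
        if (l > 1L) grad_a <- t(layer$W) %*% grad_z
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        params$layers[[l]]$W <- layer$W -
          learning_rate * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + adam_eps)
        params$layers[[l]]$b <- layer$b -
          learning_rate * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + adam_eps)
      }
    }
    history[epoch] <- epoch_loss / m
    if (verbose) {
      message(sprintf("epoch %d/%d: loss %.6f", epoch, epochs, history[epoch]))
    }
  }
  list(params = params, history = history)
}
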