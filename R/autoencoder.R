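#' Training configuration for the autoencoder
#'
#' Defaults follow the reference recipe: Adam for 100 epochs with 10%
#' dropout and an L2 weight penalty of `alpha = 1e-6`. Batch size and the
#' Adam hyperparameters use conventional values.
#'
#' @param epochs Number of full passes over the training data.
#' @param l2_alpha L2 penalty coefficient on the weight matrices.
#' @param dropout_rate Dropout probability on the wide hidden layers.
#' @param batch_size Minibatch size.
#' @param learning_rate,beta1,beta2,adam_eps Adam hyperparameters.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return A list of class `TrainConfig`.
#' @export
train_config <- function(epochs = 100L, l2_alpha = 1e-6, dropout_rate = 0.10,
                         batch_size = 256L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L) {
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (l2_alpha < 0) stop("`l2_alpha` must be >= 0")
  structure(list(epochs = as.integer(epochs), l2_alpha = l2_alpha,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Build the autoencoder layer stack
#'
#' Symmetric sigmoid architecture: hidden widths (default 500-100-500)
#' followed by a sigmoid output layer of `input_dim` units, so the
#' reconstruction lives in (0, 1) and matches data scaled with
#' [minmax_to_unit()]. Dropout is placed on the wide hidden layers only —
#' never on the bottleneck, whose activations feed attribution and
#' clustering, and never at inference.
#'
#' @param input_dim Number of genes.
#' @param hidden_widths Integer vector of hidden-layer widths; the narrowest
#'   is the bottleneck.
#' @param dropout_rate Dropout probability for the non-bottleneck hidden
#'   layers.
#' @return A list of [layer_spec()] objects.
#' @export
ae_architecture <- function(input_dim, hidden_widths = c(500L, 100L, 500L),
                            dropout_rate = 0.10) {
  bottleneck <- which.min(hidden_widths)
  layers <- lapply(seq_along(hidden_widths), function(l) {
    layer_spec(hidden_widths[l], "sigmoid",
               dropout_rate = if (l == bottleneck) 0 else dropout_rate)
  })
  c(layers, list(layer_spec(input_dim, "sigmoid", dropout_rate = 0)))
}

#' Train the autoencoder
#'
#' Minimizes mean absolute reconstruction error plus an L2 weight penalty
#' with Adam. The input must already be on the unit scale (see
#' [minmax_to_unit()]); the sigmoid output layer reconstructs it directly.
#' Training is seed-reproducible.
#'
#' @param X_train An `ExpressionMatrix` with values in \[0, 1\].
#' @param hidden_widths Hidden-layer widths, narrowest = bottleneck.
#' @param config A [train_config()].
#' @return A `NetworkParams` object with attributes `history` (per-epoch
#'   mean training loss) and `gene_ids`.
#' @export
train_autoencoder <- function(X_train, hidden_widths = c(500L, 100L, 500L),
                              config = train_config()) {
  v <- as_plain_matrix(X_train)
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    stop("X_train must be scaled to [0, 1]; see minmax_to_unit()")
  }
  arch <- ae_architecture(nrow(v), hidden_widths, config$dropout_rate)
  params <- init_network(nrow(v), arch, seed = config$seed)
  fit <- nn_train(params, v, v, loss = "mae", epochs = config$epochs,
                  batch_size = config$batch_size, l2_alpha = config$l2_alpha,
                  learning_rate = config$learning_rate, beta1 = config$beta1,
                  beta2 = config$beta2, adam_eps = config$adam_eps,
                  seed = config$seed)
  out <- fit$params
  attr(out, "history") <- fit$history
  attr(out, "gene_ids") <- rownames(X_train)
  attr(out, "train_config") <- config
  out
}

#' Reconstruct inputs through the full autoencoder
#'
#' @param params Trained `NetworkParams`.
#' @param x Numeric vector (one profile) or matrix (genes x samples).
#' @return Reconstruction with the same shape as `x`, values in (0, 1).
#' @export
reconstruct <- function(params, x) {
  fw <- nn_forward(params, x)
  fw$activations[[length(fw$activations)]]
}

#' Encode inputs to the bottleneck representation
#'
#' @param params Trained `NetworkParams`.
#' @param x Numeric vector or matrix (genes x samples).
#' @return Bottleneck activations: a vector, or a matrix with bottleneck
#'   units in rows and samples in columns.
#' @export
encode <- function(params, x) {
  fw <- nn_forward(params, x, n_layers = params$bottleneck_index)
  fw$activations[[params$bottleneck_index]]
}

#' Autoencoder loss: mean absolute error plus L2 weight penalty
#'
#' `mean(|g - g_hat|) + l2_alpha * sum_j ||W_j||_F^2`, biases excluded from
#' the penalty.
#'
#' @param g,g_hat Numeric vectors of equal length (or matrices of equal
#'   shape).
#' @param params `NetworkParams` whose weight matrices enter the penalty.
#' @param l2_alpha Penalty coefficient.
#' @return A single number.
#' @export
ae_loss <- function(g, g_hat, params, l2_alpha = 1e-6) {
  if (length(g) != length(g_hat)) stop("`g` and `g_hat` lengths differ")
  pen <- l2_alpha * sum(vapply(params$layers, function(l) sum(l$W^2),
                               numeric(1)))
  mean(abs(g - g_hat)) + pen
}

#' Save or load a trained model archive
#'
#' The archive stores layer widths, activation tags, weights, biases, the
#' expression-scale bounds, and the training configuration, and round-trips
#' bit-exactly.
#'
#' @param model A `NetworkParams` or `InferenceModel`, optionally with
#'   scaling bounds attached.
#' @param path File path for the archive.
#' @param low,high Expression-scale bounds stored alongside the parameters.
#' @return `load_model()` returns the saved object with bounds in
#'   `attr(, "scale_bounds")`.
#' @export
save_model <- function(model, path, low = 4, high = 15) {
  attr(model, "scale_bounds") <- c(low = low, high = high)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
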