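#' Partition an expression matrix into landmark and target rows
#'
#' Target genes are every gene not in the landmark set; both halves keep the
#' original sample order. Landmark rows are returned in landmark rank order.
#'
#' @param X An `ExpressionMatrix` containing every landmark gene.
#' @param landmarks A `LandmarkSet` or character vector of gene ids.
#' @return A list with `landmark` and `target` expression matrices.
#' @export
split_landmark_target <- function(X, landmarks) {
  ids <- if (inherits(landmarks, "LandmarkSet")) landmarks$gene_ids else
    as.character(landmarks)
  if (length(ids) < 1L) stop("landmark set must contain at least one gene")
  missing <- setdiff(ids, rownames(X))
  if (length(missing) > 0) {
    stop(sprintf("landmark ids absent from the matrix: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  target_ids <- setdiff(rownames(X), ids)
  list(landmark = X[ids, ], target = X[target_ids, ])
}

#' Specification of the landmark-to-target regressor
#'
#' A feed-forward network mapping landmark expression to target expression,
#' trained with mean squared error. The desk-scale default is one hidden
#' layer of 200 tanh units with a linear output; `full_scale = TRUE`
#' switches to a single 9000-unit hidden layer, the scale used for
#' full-compendium inference.
#'
#' @param hidden_widths Integer vector of hidden widths (may be empty for a
#'   purely linear model).
#' @param hidden_activation `"tanh"` or `"sigmoid"`.
#' @param epochs,batch_size,learning_rate,seed Training controls (Adam).
#' @param l2_alpha L2 penalty on the weights.
#' @param full_scale If `TRUE`, use the full-scale single hidden layer of
#'   9000 units.
#' @return A list of class `RegressorSpec`.
#' @export
regressor_spec <- function(hidden_widths = 200L,
                           hidden_activation = c("tanh", "sigmoid"),
                           epochs = 200L, batch_size = 256L,
                           learning_rate = 1e-3, l2_alpha = 0,
                           seed = 1L, full_scale = FALSE) {
  hidden_activation <- match.arg(hidden_activation)
  if (full_scale) hidden_widths <- 9000L
  structure(list(hidden_widths = as.integer(hidden_widths),
                 hidden_activation = hidden_activation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l2_alpha = l2_alpha,
                 seed = as.integer(seed)),
            class = "RegressorSpec")
}

#' Train the landmark-to-target expression regressor
#'
#' Both matrices are rescaled to the unit interval using their stated
#' expression bounds before fitting, and predictions are mapped back for
#' reporting. Training minimizes mean squared error with Adam and is
#' seed-reproducible.
#'
#' @param landmark_X Landmark `ExpressionMatrix` (genes x samples).
#' @param target_X Target `ExpressionMatrix` over the same samples.
#' @param spec A [regressor_spec()].
#' @param low,high Expression-scale bounds used for the unit rescale.
#' @return A list of class `InferenceModel` holding the fitted
#'   `NetworkParams`, landmark/target gene ids, scale bounds, and the
#'   training-loss history.
#' @export
train_regressor <- function(landmark_X, target_X, spec = regressor_spec(),
                            low = 4, high = 15) {
  if (!identical(colnames(landmark_X), colnames(target_X))) {
    stop("landmark and target matrices must share identical sample columns")
  }
  if (length(intersect(rownames(landmark_X), rownames(target_X))) > 0) {
    stop("landmark and target gene sets must be disjoint")
  }
  Xu <- (as_plain_matrix(landmark_X) - low) / (high - low)
  Yu <- (as_plain_matrix(target_X) - low) / (high - low)
  layers <- lapply(spec$hidden_widths, function(w) {
    layer_spec(w, spec$hidden_activation)
  })
  layers <- c(layers, list(layer_spec(nrow(Yu), "linear")))
  params <- init_network(nrow(Xu), layers, seed = spec$seed)
  fit <- nn_train(params, Xu, Yu, loss = "mse", epochs = spec$epochs,
                  batch_size = spec$batch_size, l2_alpha = spec$l2_alpha,
                  learning_rate = spec$learning_rate, seed = spec$seed)
  structure(list(params = fit$params,
                 landmark_gene_ids = rownames(landmark_X),
                 target_gene_ids = rownames(target_X),
                 low = low, high = high,
                 history = fit$history,
                 spec = spec),
            class = "InferenceModel")
}

#' Predict target-gene expression from landmark expression
#'
#' Landmark rows are matched by gene id (order enforced by id, not
#' position); the output is returned on the original expression scale.
#'
#' @param model An `InferenceModel`.
#' @param landmark_X An `ExpressionMatrix` containing every landmark gene of
#'   the model.
#' @return An `ExpressionMatrix`, target genes x samples.
#' @export
predict_targets <- function(model, landmark_X) {
  missing <- setdiff(model$landmark_gene_ids, rownames(landmark_X))
  if (length(missing) > 0) {
    stop(sprintf("missing landmark genes: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  Xu <- (as_plain_matrix(landmark_X[model$landmark_gene_ids, ]) - model$low) /
    (model$high - model$low)
  fw <- nn_forward(model$params, Xu)
  Yu <- fw$activations[[length(fw$activations)]]
  out <- model$low + (model$high - model$low) * Yu
  expression_matrix(out, gene_ids = model$target_gene_ids,
                    sample_ids = colnames(landmark_X))
}
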