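#' DeepLIFT Rescale multiplier of an activation
#'
#' The finite-difference slope of the activation between the reference
#' pre-activation `x0` and the actual pre-activation `x`:
#' `(f(x) - f(x0)) / (x - x0)`. When the pre-activation difference is
#' smaller than `epsilon` the slope is numerically unstable and the analytic
#' derivative `f'(x0)` is used instead (the gradient fallback).
#'
#' @param x,x0 Actual and reference pre-activation (vectorized).
#' @param activation `"sigmoid"` or `"linear"`.
#' @param epsilon Fallback threshold on `|x - x0|`.
#' @return Multiplier(s), same shape as `x`.
#' @export
rescale_multiplier <- function(x, x0, activation, epsilon = 1e-7) {
  if (!activation %in% c("sigmoid", "linear", "tanh")) {
    stop(sprintf("unknown activation tag '%s'", activation))
  }
  if (activation == "linear") {
    out <- x
    out[] <- 1
    return(out)
  }
  fx <- activation_fun(x, activation)
  fx0 <- activation_fun(x0, activation)
  dx <- x - x0
  small <- abs(dx) < epsilon
  m <- (fx - fx0) / ifelse(small, 1, dx)
  if (any(small)) {
    m[small] <- activation_deriv(fx0, activation)[small]
  }
  m
}

#' Reference input for attribution
#'
#' DeepLIFT measures each gene's contribution as a difference from a
#' reference profile. The default reference is the per-gene mean of the
#' training data, so importance measures deviation from typical expression.
#'
#' @param values Numeric vector on the unit scale, one entry per gene.
#' @param source Tag recording where the reference came from.
#' @return A list of class `ReferenceInput`.
#' @export
reference_input <- function(values, source = c("custom", "train_mean", "zeros")) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (any(values < 0 | values > 1)) stop("reference values must lie in [0, 1]")
  structure(list(values = values, source = source), class = "ReferenceInput")
}

#' @rdname reference_input
#' @param X_train An `ExpressionMatrix` on the unit scale; the reference is
#'   its per-gene mean.
#' @export
reference_from_training <- function(X_train) {
  if (nrow(X_train) == 0 || ncol(X_train) == 0) stop("empty training matrix")
  reference_input(rowMeans(as_plain_matrix(X_train)), source = "train_mean")
}

#' Propagate Rescale-rule contributions from inputs to the bottleneck
#'
#' Chains multipliers backward from every bottleneck unit to every input
#' gene through the encoder sub-network only: linear weight matrices
#' contribute themselves, each sigmoid unit contributes its
#' [rescale_multiplier()] evaluated at the actual vs. reference
#' pre-activation. The contribution of gene `i` to bottleneck unit `t` is
#' the chained multiplier times `(x_i - ref_i)`, which guarantees the
#' summation-to-delta identity: contributions to unit `t` sum exactly to
#' `encode(x)_t - encode(ref)_t`.
#'
#' @param params Trained `NetworkParams` (the decoder layers are ignored).
#' @param x Numeric vector on the unit scale, one value per input gene.
#' @param ref A `ReferenceInput` (or numeric vector on the unit scale).
#' @param tol Tolerance for unit-scale range checking of `x`.
#' @return Numeric matrix, input genes x bottleneck units.
#' @export
propagate_contributions <- function(params, x, ref, tol = 1e-6) {
  check_network(params)
  if (is.numeric(ref)) ref <- reference_input(ref)
  r <- ref$values
  if (length(x) != params$input_dim || length(r) != params$input_dim) {
    stop("input and reference must have one value per input gene")
  }
  if (min(x) < -tol || max(x) > 1 + tol) {
    stop("input x must be on the unit scale [0, 1]")
  }
  enc_layers <- seq_len(params$bottleneck_index)
  fw_x <- nn_forward(params, x, n_layers = params$bottleneck_index,
                     keep_preactivations = TRUE)
  fw_r <- nn_forward(params, r, n_layers = params$bottleneck_index,
                     keep_preactivations = TRUE)
  M <- NULL  # multiplier matrix: bottleneck units x current layer inputs
  for (l in rev(enc_layers)) {
    layer <- params$layers[[l]]
    d_l <- rescale_multiplier(fw_x$preactivations[[l]],
                              fw_r$preactivations[[l]],
                              layer$activation)
    scaled <- d_l * layer$W   # row i of W scaled by unit i's multiplier
    M <- if (is.null(M)) scaled else M %*% scaled
  }
  C <- t(M) * (x - r)
  dimnames(C) <- NULL
  C
}

#' Contribution tensor over a set of samples
#'
#' Applies [propagate_contributions()] to every sample column and stacks the
#' results into a 3-d array indexed (sample, input gene, bottleneck unit).
#' A seeded subsample of columns can be used for large inputs.
#'
#' @param params Trained `NetworkParams`.
#' @param X An `ExpressionMatrix` on the unit scale.
#' @param ref A `ReferenceInput`; defaults to the per-gene mean of `X`.
#' @param n_subsample Optional number of sample columns to use.
#' @param seed Seed for the subsample draw.
#' @return Array of class `ContributionTensor`, dim
#'   `(n_samples, n_genes, n_bottleneck)`, with sample and gene dimnames.
#' @export
contribution_tensor <- function(params, X, ref = reference_from_training(X),
                                n_subsample = NULL, seed = 1L) {
  v <- as_plain_matrix(X)
  cols <- seq_len(ncol(v))
  if (!is.null(n_subsample) && n_subsample < ncol(v)) {
    set.seed(as.integer(seed))
    cols <- sort(sample.int(ncol(v), n_subsample))
  }
  n_units <- nrow(params$layers[[params$bottleneck_index]]$W)
  out <- array(NA_real_, dim = c(length(cols), nrow(v), n_units),
               dimnames = list(colnames(X)[cols], rownames(X), NULL))
  for (s in seq_along(cols)) {
    out[s, , ] <- propagate_contributions(params, v[, cols[s]], ref)
  }
  class(out) <- c("ContributionTensor", class(out))
  out
}

#' Aggregate contributions into a gene importance ranking
#'
#' Each gene's importance is the mean of its absolute contribution scores
#' over all samples and bottleneck units. Absolute values are taken before
#' averaging so that opposing effects across units and samples do not
#' cancel; signed averaging is available via `signed = TRUE`. Ties are
#' broken by ascending gene identifier for determinism.
#'
#' @param C A `ContributionTensor` from [contribution_tensor()].
#' @param signed If `TRUE`, average signed scores and rank by the absolute
#'   value of that average.
#' @return A data.frame of class `ImportanceRanking` with columns `gene_id`
#'   and `score`, sorted by descending score.
#' @export
aggregate_importance <- function(C, signed = FALSE) {
  if (length(C) == 0) stop("empty contribution tensor")
  if (!all(is.finite(C))) stop("contribution tensor contains non-finite values")
  genes <- dimnames(C)[[2]]
  score <- if (signed) {
    abs(apply(C, 2L, mean))
  } else {
    apply(abs(C), 2L, mean)
  }
  ord <- order(-score, genes)
  out <- data.frame(gene_id = genes[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ImportanceRanking", class(out))
  out
}

#' Select the top-k landmark genes
#'
#' Takes the first `k` genes of an importance ranking, preserving rank
#' order. The default `k = 943` mirrors the size of the L1000 landmark set.
#'
#' @param ranking An `ImportanceRanking`.
#' @param k Number of landmarks, between 1 and the size of the ranking.
#' @return A list of class `LandmarkSet` with `gene_ids` (rank order),
#'   `scores`, and `k`.
#' @export
select_landmarks <- function(ranking, k = 943L) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranking)) {
    stop(sprintf("k must be between 1 and %d", nrow(ranking)))
  }
  structure(list(gene_ids = ranking$gene_id[seq_len(k)],
                 scores = ranking$score[seq_len(k)],
                 k = k),
            class = "LandmarkSet")
}

#' Write an importance ranking as a (rank, gene_id, score) TSV
#'
#' @param ranking An `ImportanceRanking`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ranking, path) {
  dt <- data.table::data.table(rank = seq_len(nrow(ranking)),
                               gene_id = ranking$gene_id,
                               score = ranking$score)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
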