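#' Configuration of the synthetic expression generator
#'
#' The generator emulates the structure the landmark framework assumes: a
#' few latent factors drive a minority of "influential" genes through
#' monotone nonlinearities; a majority of redundant follower genes are
#' nonlinear functions of those drivers; some genes are pure independent
#' noise; and the full matrix is mapped into the conventional \[4, 15\]
#' log-expression range.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_factors Number of latent factors K (each driver loads on one).
#' @param n_driver_genes Number of driver genes (>= K so every factor is
#'   represented).
#' @param n_noise_genes Number of pure-noise genes; the remainder are
#'   followers.
#' @param follower_fanout How many drivers each follower mixes.
#' @param noise_sd Additive Gaussian noise on drivers and followers, on the
#'   pre-rescale scale where the nonlinear signals span roughly (0, 1).
#' @param noise_gene_sd Standard deviation of the pure-noise genes, on the
#'   same pre-rescale scale (mean 0.5), so that variance alone does not
#'   separate gene classes.
#' @param nonlinearity Monotone nonlinearity tag: `"sigmoid"`, `"tanh"`, or
#'   `"cubic"`.
#' @param group_means Optional numeric matrix (groups x K) of factor-space
#'   group centroids; samples are then assigned to labeled groups.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 1000L, n_samples = 400L,
                             n_factors = 10L, n_driver_genes = 50L,
                             n_noise_genes = 200L, follower_fanout = 3L,
                             noise_sd = 0.1, noise_gene_sd = 0.2,
                             nonlinearity = c("sigmoid", "tanh", "cubic"),
                             group_means = NULL, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_driver_genes + n_noise_genes > n_genes) {
    stop("n_driver_genes + n_noise_genes must not exceed n_genes")
  }
  if (n_factors > n_driver_genes) stop("n_factors must be <= n_driver_genes")
  if (!is.null(group_means)) {
    group_means <- as.matrix(group_means)
    if (ncol(group_means) != n_factors) {
      stop("group_means must have n_factors columns")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_factors = as.integer(n_factors),
                 n_driver_genes = as.integer(n_driver_genes),
                 n_noise_genes = as.integer(n_noise_genes),
                 follower_fanout = as.integer(follower_fanout),
                 noise_sd = noise_sd, noise_gene_sd = noise_gene_sd,
                 nonlinearity = nonlinearity, group_means = group_means,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

nonlinearity_fun <- function(tag) {
  switch(tag,
         sigmoid = function(u) 1 / (1 + exp(-u)),
         tanh = function(u) tanh(u),
         cubic = function(u) u^3,
         stop(sprintf("unknown nonlinearity '%s'", tag)))
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Per sample, latent factors `z ~ N(0, I)` are drawn (shifted by a group
#' centroid if labeled groups are configured). Each driver gene is a
#' monotone nonlinearity of one factor with a gene-specific loading drawn
#' from `+/- Uniform(0.5, 2)`, plus Gaussian noise; each follower gene is
#' the nonlinearity of a weighted sum of `follower_fanout` randomly chosen
#' drivers, plus noise; noise genes are independent Gaussians. Gene classes
#' are assigned to random row positions. Finally the whole matrix is
#' affinely mapped onto exactly \[4, 15\].
#'
#' @param config A [synthetic_config()].
#' @return A list with `expression` (an [expression_matrix()]) and `truth`
#'   (a `SyntheticTruth` list with the gene classes, follower parents,
#'   loadings, factor assignments and optional sample group labels).
#' @export
generate_expression <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$n_samples
  K <- config$n_factors
  D <- config$n_driver_genes
  Nn <- config$n_noise_genes
  Fo <- n - D - Nn
  nl <- nonlinearity_fun(config$nonlinearity)

  gene_names <- sprintf("G%04d", seq_len(n))
  perm <- sample.int(n)
  driver_rows <- perm[seq_len(D)]
  noise_rows <- perm[D + seq_len(Nn)]
  follower_rows <- if (Fo > 0) perm[D + Nn + seq_len(Fo)] else integer(0)

  labels <- NULL
  if (!is.null(config$group_means)) {
    n_groups <- nrow(config$group_means)
    labels <- rep_len(seq_len(n_groups), m)
    Z <- matrix(stats::rnorm(K * m), nrow = K) +
      t(config$group_means[labels, , drop = FALSE])
  } else {
    Z <- matrix(stats::rnorm(K * m), nrow = K)
  }

  factor_of_driver <- rep_len(seq_len(K), D)
  loadings <- sample(c(-1, 1), D, replace = TRUE) * stats::runif(D, 0.5, 2)
  driver_vals <- nl(loadings * Z[factor_of_driver, , drop = FALSE])
  if (config$noise_sd > 0) {
    driver_vals <- driver_vals +
      matrix(stats::rnorm(D * m, sd = config$noise_sd), nrow = D)
  }

  X <- matrix(NA_real_, nrow = n, ncol = m)
  X[driver_rows, ] <- driver_vals
  X[noise_rows, ] <- matrix(stats::rnorm(Nn * m, mean = 0.5,
                                         sd = config$noise_gene_sd),
                            nrow = Nn)

  parents <- list()
  if (Fo > 0) {
    fan <- min(config$follower_fanout, D)
    for (f in seq_len(Fo)) {
      par_idx <- sample.int(D, fan)
      w <- sample(c(-1, 1), fan, replace = TRUE) * stats::runif(fan, 0.5, 2)
      vals <- nl(drop(crossprod(driver_vals[par_idx, , drop = FALSE], w)))
      if (config$noise_sd > 0) {
        vals <- vals + stats::rnorm(m, sd = config$noise_sd)
      }
      X[follower_rows[f], ] <- vals
      parents[[gene_names[follower_rows[f]]]] <- gene_names[driver_rows[par_idx]]
    }
  }

  rng <- range(X)
  X <- 4 + 11 * (X - rng[1]) / (rng[2] - rng[1])
  expr <- expression_matrix(X, gene_ids = gene_names,
                            sample_ids = sprintf("S%04d", seq_len(m)))
  truth <- structure(list(
    driver_gene_ids = gene_names[driver_rows],
    follower_gene_ids = gene_names[follower_rows],
    follower_parents = parents,
    noise_gene_ids = gene_names[noise_rows],
    factor_of_driver = stats::setNames(factor_of_driver,
                                       gene_names[driver_rows]),
    loadings = stats::setNames(loadings, gene_names[driver_rows]),
    group_labels = if (!is.null(labels)) {
      stats::setNames(labels, colnames(expr))
    },
    config = config), class = "SyntheticTruth")
  list(expression = expr, truth = truth)
}

#' Score how well a landmark set recovers the true driver genes
#'
#' Counts selected genes that are ground-truth drivers and reports the fold
#' enrichment over the hypergeometric expectation `k * D / N` for a random
#' draw of the same size.
#'
#' @param landmarks A `LandmarkSet` or character vector of gene ids.
#' @param truth A `SyntheticTruth` from [generate_expression()].
#' @return A list with `n_drivers_recovered`, `fold_enrichment`, and the
#'   hypergeometric `expected` count.
#' @export
recovery_score <- function(landmarks, truth) {
  ids <- if (inherits(landmarks, "LandmarkSet")) landmarks$gene_ids else
    as.character(landmarks)
  if (length(ids) < 1L) stop("empty landmark set")
  N <- length(truth$driver_gene_ids) + length(truth$follower_gene_ids) +
    length(truth$noise_gene_ids)
  universe <- c(truth$driver_gene_ids, truth$follower_gene_ids,
                truth$noise_gene_ids)
  if (!all(ids %in% universe)) stop("landmarks outside the gene universe")
  D <- length(truth$driver_gene_ids)
  k <- length(ids)
  n_rec <- length(intersect(ids, truth$driver_gene_ids))
  expected <- k * D / N
  list(n_drivers_recovered = n_rec,
       fold_enrichment = n_rec / expected,
       expected = expected)
}

#' Serialize or restore synthetic ground truth as structured text
#'
#' @param truth A `SyntheticTruth`.
#' @param path JSON file path.
#' @return `read_truth()` returns a `SyntheticTruth` (without the original
#'   config object).
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$follower_parents <- as.list(x$follower_parents)
  structure(x, class = "SyntheticTruth")
}
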