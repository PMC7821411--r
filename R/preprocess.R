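#' Quantile normalize an expression matrix to a fixed range
#'
#' Forces every sample (column) onto the common distribution of cross-sample
#' mean order statistics — the classic quantile-normalization construction,
#' with average-rank handling of ties — and then applies a single global
#' affine rescale so the matrix spans exactly `[low, high]`. The default
#' target range of \[4, 15\] is the conventional log-scale range for
#' microarray compendia.
#'
#' @param X An [expression_matrix()] with at least 2 genes and 2 samples.
#' @param low,high Target global minimum and maximum after rescaling.
#' @return An `ExpressionMatrix` in which every column has the identical
#'   multiset of values (for tie-free input) and the global range is exactly
#'   `[low, high]`.
#' @export
quantile_normalize <- function(X, low = 4, high = 15) {
  if (ncol(X) < 2) stop("quantile normalization needs >= 2 samples")
  if (nrow(X) < 2) stop("quantile normalization needs >= 2 genes")
  if (high <= low) stop("`high` must exceed `low`")
  mu <- rowMeans(apply(as_plain_matrix(X), 2L, sort))
  out <- map_columns_to_reference(as_plain_matrix(X), mu)
  rng <- range(out)
  if (rng[2] == rng[1]) stop("constant matrix: cannot rescale a zero range")
  out <- low + (high - low) * (out - rng[1]) / (rng[2] - rng[1])
  expression_matrix(out, gene_ids = rownames(X), sample_ids = colnames(X))
}

# Assign each column the reference order statistics at its (possibly
# fractional, tie-averaged) ranks; tie-free columns get `ref` exactly.
map_columns_to_reference <- function(vals, ref) {
  n <- nrow(vals)
  ref <- sort(ref)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    rk <- rank(vals[, j], ties.method = "average")
    if (n == 1L) {
      out[, j] <- ref
    } else {
      out[, j] <- stats::approx(seq_len(n), ref, xout = rk)$y
    }
  }
  out
}

#' Build a reference distribution from a normalized training matrix
#'
#' Stores the training set's cross-sample mean order statistics so that
#' samples from a new platform can be mapped onto the same distribution
#' (joint quantile normalization against a frozen reference).
#'
#' @param X A normalized `ExpressionMatrix`.
#' @return Non-decreasing numeric vector of length `n_genes(X)`.
#' @export
build_reference_distribution <- function(X) {
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty matrix: no reference to build")
  unname(sort(rowMeans(apply(as_plain_matrix(X), 2L, sort))))
}

#' Map a matrix onto a stored reference distribution
#'
#' Each column is replaced by the reference order statistics at its ranks.
#' Applying a reference back to the already-normalized matrix it was built
#' from is the identity.
#'
#' @param X An `ExpressionMatrix` whose gene count matches the reference.
#' @param ref Non-decreasing numeric vector from
#'   [build_reference_distribution()].
#' @return An `ExpressionMatrix` whose columns follow `ref`.
#' @export
apply_reference_distribution <- function(X, ref) {
  if (length(ref) != nrow(X)) {
    stop("reference length must equal the number of genes")
  }
  out <- map_columns_to_reference(as_plain_matrix(X), ref)
  expression_matrix(out, gene_ids = rownames(X), sample_ids = colnames(X))
}

#' Remove duplicated expression profiles via clustered correlation scanning
#'
#' Samples are partitioned by seeded k-means (k-means++ initialization, Lloyd
#' iterations) on their expression vectors; within each cluster, samples are
#' scanned in input order and a sample is retained only if its Pearson
#' correlation with every already-retained sample of that cluster stays below
#' `corr_threshold`. k-means is purely an accelerator: with `n_clusters = 1`
#' the operation reduces to the exhaustive pairwise scan that defines
#' correctness.
#'
#' @param X An `ExpressionMatrix`.
#' @param n_clusters Number of k-means clusters (1 disables clustering).
#' @param corr_threshold Correlation at or above which a profile counts as a
#'   duplicate; must be in (0, 1].
#' @param seed Integer seed for the k-means initialization.
#' @return An `ExpressionMatrix` of the retained samples, in original order.
#' @export
deduplicate_profiles <- function(X, n_clusters = min(100L, ncol(X)),
                                 corr_threshold = 0.99, seed = 1L) {
  if (corr_threshold <= 0 || corr_threshold > 1) {
    stop("`corr_threshold` must be in (0, 1]")
  }
  if (n_clusters < 1 || n_clusters > ncol(X)) {
    stop("`n_clusters` must be between 1 and the number of samples")
  }
  m <- ncol(X)
  if (m == 1L) return(X)
  cl <- if (n_clusters == 1L) rep(1L, m) else {
    kmeans_pp(t(as_plain_matrix(X)), k = n_clusters, seed = seed)$cluster
  }
  keep <- logical(m)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    retained <- integer(0)
    for (i in idx) {
      dup <- FALSE
      for (r in retained) {
        if (stats::cor(X[, i], X[, r]) >= corr_threshold) {
          dup <- TRUE
          break
        }
      }
      if (!dup) retained <- c(retained, i)
    }
    keep[retained] <- TRUE
  }
  X[, which(keep)]
}

# Seeded k-means with k-means++ seeding and Lloyd iterations.
kmeans_pp <- function(pts, k, seed = 1L, iter_max = 300L) {
  set.seed(as.integer(seed))
  n <- nrow(pts)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(pts, 2L, pts[centers[1], ], "-")^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1L, prob = probs)
      d2 <- pmin(d2, rowSums(sweep(pts, 2L, pts[centers[j], ], "-")^2))
    }
  }
  stats::kmeans(pts, centers = pts[centers, , drop = FALSE],
                iter.max = iter_max, algorithm = "Lloyd")
}

#' Seeded train/test split of samples
#'
#' Uniformly random, seed-reproducible partition of the sample columns.
#' The training set size is `floor(n_samples * train_fraction)`.
#'
#' @param X An `ExpressionMatrix` with at least 2 samples.
#' @param train_fraction Fraction of samples assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `SplitResult` with elements `train`, `test`
#'   (both `ExpressionMatrix`) and `seed`.
#' @export
train_test_split <- function(X, train_fraction = 0.9, seed = 1L) {
  if (ncol(X) < 2) stop("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be strictly between 0 and 1")
  }
  m <- ncol(X)
  n_train <- floor(m * train_fraction)
  if (n_train < 1 || n_train >= m) {
    stop("split leaves an empty train or test set")
  }
  set.seed(as.integer(seed))
  train_idx <- sort(sample.int(m, n_train))
  out <- list(train = X[, train_idx],
              test = X[, setdiff(seq_len(m), train_idx)],
              seed = as.integer(seed))
  class(out) <- "SplitResult"
  out
}

#' Affine rescaling between the expression range and the unit interval
#'
#' A sigmoid output layer can only emit values in (0, 1), so expression
#' values in `[low, high]` are mapped to \[0, 1\] before training and mapped
#' back for reporting. Values may stray outside the range by at most `tol`
#' (they are clamped); anything further out is refused.
#'
#' @param X An `ExpressionMatrix`.
#' @param low,high The expression-scale bounds.
#' @param tol Tolerance for values slightly outside the bounds.
#' @return An `ExpressionMatrix` on the transformed scale.
#' @export
minmax_to_unit <- function(X, low = 4, high = 15, tol = 1e-9) {
  v <- as_plain_matrix(X)
  if (min(v) < low - tol || max(v) > high + tol) {
    stop(sprintf("values outside [%g, %g] (tolerance %g)", low, high, tol))
  }
  out <- pmin(pmax((v - low) / (high - low), 0), 1)
  expression_matrix(out, gene_ids = rownames(X), sample_ids = colnames(X))
}

#' @rdname minmax_to_unit
#' @export
unit_to_minmax <- function(X, low = 4, high = 15, tol = 1e-9) {
  v <- as_plain_matrix(X)
  if (min(v) < -tol || max(v) > 1 + tol) {
    stop(sprintf("values outside [0, 1] (tolerance %g)", tol))
  }
  out <- low + (high - low) * pmin(pmax(v, 0), 1)
  expression_matrix(out, gene_ids = rownames(X), sample_ids = colnames(X))
}
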