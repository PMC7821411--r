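#' Per-gene mean absolute error
#'
#' For each gene `j`, `MAE_j = mean_i |g_ij - ghat_ij|` across samples, in
#' expression units.
#'
#' @param G Observed `ExpressionMatrix`.
#' @param G_hat Predicted `ExpressionMatrix`, aligned with `G`.
#' @return Named numeric vector, one value per gene.
#' @export
mae_per_gene <- function(G, G_hat) {
  stopifnot_aligned(G, G_hat)
  rowMeans(abs(as_plain_matrix(G) - as_plain_matrix(G_hat)))
}

#' Per-gene Pearson correlation
#'
#' Pearson `r` between the observed and predicted expression of each gene
#' across samples. A gene that is constant on either side has no defined
#' correlation; it is reported as 0 and flagged in the `undefined`
#' attribute rather than propagating `NaN`.
#'
#' @inheritParams mae_per_gene
#' @return Named numeric vector of correlations in \[-1, 1\] with a logical
#'   attribute `undefined` marking constant genes.
#' @export
pcc_per_gene <- function(G, G_hat) {
  stopifnot_aligned(G, G_hat)
  if (ncol(G) < 3) stop("need >= 3 samples for a meaningful correlation")
  g <- as_plain_matrix(G)
  h <- as_plain_matrix(G_hat)
  gc <- g - rowMeans(g)
  hc <- h - rowMeans(h)
  sg <- sqrt(rowSums(gc^2))
  sh <- sqrt(rowSums(hc^2))
  undef <- sg == 0 | sh == 0
  denom <- sg * sh
  denom[undef] <- 1
  r <- rowSums(gc * hc) / denom
  r[undef] <- 0
  r <- pmin(pmax(r, -1), 1)
  names(r) <- rownames(G)
  attr(r, "undefined") <- unname(undef)
  r
}

#' Cross-gene permutation test for predicted-vs-observed similarity
#'
#' A high Pearson correlation between gene `j` and its prediction is only
#' meaningful relative to how easily the prediction correlates with
#' unrelated genes. The reference distribution is the set of correlations
#' between the predicted profile `ghat_j` and every *other* observed gene
#' `g_i`, `i != j`; the p-value is the fraction of that reference at or
#' above the self-correlation (ties count against significance).
#' Significance requires `p < alpha` strictly.
#'
#' @inheritParams mae_per_gene
#' @param gene Gene id or row index to test.
#' @param alpha Significance threshold (default 0.01).
#' @return A list with `p`, `significant`, and the self-correlation `r`.
#' @export
permutation_test <- function(G, G_hat, gene, alpha = 0.01) {
  stopifnot_aligned(G, G_hat)
  if (nrow(G) < 2) stop("permutation test needs >= 2 genes for a reference")
  j <- if (is.character(gene)) match(gene, rownames(G)) else as.integer(gene)
  if (is.na(j) || j < 1 || j > nrow(G)) stop("unknown gene")
  g <- as_plain_matrix(G)
  ghat_j <- as_plain_matrix(G_hat)[j, ]
  r_all <- suppressWarnings(as.vector(stats::cor(t(g), ghat_j)))
  r_all[is.na(r_all)] <- 0
  r_self <- r_all[j]
  ref <- r_all[-j]
  p <- mean(ref >= r_self)
  list(p = p, significant = is.finite(r_self) && p < alpha, r = r_self)
}

# Permutation p-values for all genes at once: one n_genes x n_genes
# correlation pass instead of n calls to permutation_test().
permutation_test_all <- function(G, G_hat, alpha = 0.01) {
  g <- t(as_plain_matrix(G))
  h <- t(as_plain_matrix(G_hat))
  R <- suppressWarnings(stats::cor(g, h))   # R[i, j] = cor(g_i, ghat_j)
  R[is.na(R)] <- 0
  n <- nrow(R)
  self_r <- diag(R)
  p <- vapply(seq_len(n), function(j) mean(R[-j, j] >= self_r[j]), numeric(1))
  list(p = p, significant = p < alpha, r = self_r)
}

#' Evaluate predicted expression against observed expression
#'
#' Combines per-gene MAE, per-gene PCC, and the cross-gene permutation test
#' into one report. Genes with undefined correlation are never marked
#' significant.
#'
#' @inheritParams mae_per_gene
#' @param alpha Permutation-test significance threshold.
#' @return A list of class `EvaluationReport`: `per_gene` data.frame
#'   (`gene_id`, `mae`, `pcc`, `pcc_undefined`, `perm_p`, `significant`) and
#'   `summary` (mean MAE, mean PCC, significant-gene counts).
#' @export
evaluate_predictions <- function(G, G_hat, alpha = 0.01) {
  stopifnot_aligned(G, G_hat)
  mae <- mae_per_gene(G, G_hat)
  pcc <- pcc_per_gene(G, G_hat)
  undef <- attr(pcc, "undefined")
  perm <- permutation_test_all(G, G_hat, alpha = alpha)
  sig <- perm$significant & !undef
  per_gene <- data.frame(gene_id = rownames(G), mae = unname(mae),
                         pcc = as.vector(pcc), pcc_undefined = undef,
                         perm_p = perm$p, significant = sig,
                         stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene,
                 summary = list(mean_mae = mean(mae),
                                mean_pcc = mean(as.vector(pcc)),
                                n_significant = sum(sig),
                                n_genes = nrow(G),
                                alpha = alpha)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("EvaluationReport: %d genes\n", s$n_genes))
  cat(sprintf("  mean MAE: %.4f   mean PCC: %.4f\n", s$mean_mae, s$mean_pcc))
  cat(sprintf("  significant (perm p < %g): %d / %d\n",
              s$alpha, s$n_significant, s$n_genes))
  invisible(x)
}

#' Paired comparison of two landmark-set evaluations
#'
#' Over the genes common to both reports, computes per-gene MAE and PCC
#' deltas (A minus B), a two-sided paired t-test on each metric from its
#' closed form, and win counts. Zero-variance nonzero deltas are degenerate
#' and reported with `p = 0` and a flag.
#'
#' @param report_a,report_b `EvaluationReport` objects.
#' @return A list of class `SetComparison` with per-gene deltas and, for
#'   each metric, `t`, `p`, `zero_variance`, and win counts.
#' @export
compare_landmark_sets <- function(report_a, report_b) {
  common <- intersect(report_a$per_gene$gene_id, report_b$per_gene$gene_id)
  if (length(common) < 2) stop("need >= 2 common genes to compare")
  a <- report_a$per_gene[match(common, report_a$per_gene$gene_id), ]
  b <- report_b$per_gene[match(common, report_b$per_gene$gene_id), ]
  d_mae <- a$mae - b$mae
  d_pcc <- a$pcc - b$pcc
  structure(list(
    gene_id = common,
    delta_mae = d_mae,
    delta_pcc = d_pcc,
    mae_test = paired_t(d_mae),
    pcc_test = paired_t(d_pcc),
    wins = list(mae_a = sum(d_mae < 0), mae_b = sum(d_mae > 0),
                pcc_a = sum(d_pcc > 0), pcc_b = sum(d_pcc < 0)),
    per_gene = data.frame(gene_id = common,
                          mae_a = a$mae, mae_b = b$mae,
                          pcc_a = a$pcc, pcc_b = b$pcc,
                          stringsAsFactors = FALSE)),
    class = "SetComparison")
}

# Two-sided paired t-test from the closed form; degenerate zero-variance
# cases are flagged instead of dividing by zero.
paired_t <- function(d) {
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = n - 1L, zero_variance = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                zero_variance = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, zero_variance = FALSE)
}

#' Clustering quality of bottleneck embeddings against known labels
#'
#' Runs seeded k-means (k = number of label classes) on the embedding and
#' reports the adjusted Rand index between the induced clusters and the
#' labels, plus the mean silhouette width of the labeled classes.
#'
#' @param E Embedding matrix: bottleneck units x samples (as returned by
#'   [encode()]), or samples x dimensions.
#' @param labels Vector of class labels, one per sample.
#' @param seed Integer seed for k-means.
#' @return A list with `ari`, `silhouette`, and the cluster assignment.
#' @export
embedding_cluster_quality <- function(E, labels, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 label classes")
  pts <- if (ncol(E) == length(labels) && nrow(E) != length(labels)) t(E)
         else if (nrow(E) == length(labels)) E
         else stop("embedding dimensions do not match the labels")
  pts <- as.matrix(pts)
  km <- kmeans_pp(pts, k = nlevels(labels), seed = seed)
  sil <- cluster::silhouette(as.integer(labels), stats::dist(pts))
  list(ari = mclust::adjustedRandIndex(km$cluster, labels),
       silhouette = mean(sil[, "sil_width"]),
       cluster = km$cluster)
}

#' Write or read an evaluation report TSV
#'
#' The per-gene table is written with the summary block as commented header
#' lines (`# key value`).
#'
#' @param report An `EvaluationReport`.
#' @param path File path.
#' @return `read_report()` returns an `EvaluationReport`.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- report$summary
  writeLines(sprintf("# %s\t%s", names(s), unlist(s)), con)
  utils::write.table(report$per_gene, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "\t"))
  per_gene <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  summary <- lapply(stats::setNames(as.list(kv[, 2]), kv[, 1]),
                    utils::type.convert, as.is = TRUE)
  structure(list(per_gene = per_gene, summary = summary),
            class = "EvaluationReport")
}
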