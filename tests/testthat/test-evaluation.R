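test_that("per-gene MAE matches hand computation and an element loop", {
  G <- expression_matrix(matrix(c(1, 2, 3), 1, 3), "g1", c("a", "b", "c"))
  H <- expression_matrix(matrix(c(2, 2, 5), 1, 3), "g1", c("a", "b", "c"))
  expect_equal(unname(mae_per_gene(G, H)), 1.0)
  expect_equal(unname(mae_per_gene(G, G)), 0)

  A <- random_expression(50, 30, seed = 1)
  B <- random_expression(50, 30, seed = 2)
  B <- expression_matrix(unclass(B), rownames(A), colnames(A))
  mae <- mae_per_gene(A, B)
  loop <- numeric(50)
  for (j in 1:50) {
    acc <- 0
    for (i in 1:30) acc <- acc + abs(A[j, i] - B[j, i])
    loop[j] <- acc / 30
  }
  expect_equal(unname(mae), loop, tolerance = 1e-12)
  B_misaligned <- expression_matrix(unclass(B), rev(rownames(A)), colnames(A))
  expect_error(mae_per_gene(A, B_misaligned), "identical")
})

test_that("per-gene PCC is Pearson r with a flagged constant-gene fallback", {
  G <- random_expression(50, 30, seed = 3)
  H <- expression_matrix(unclass(G) * 2 + 1, rownames(G), colnames(G))
  expect_equal(as.vector(pcc_per_gene(G, H)), rep(1, 50), tolerance = 1e-12)
  Hn <- expression_matrix(-unclass(G), rownames(G), colnames(G))
  expect_equal(as.vector(pcc_per_gene(G, Hn)), rep(-1, 50), tolerance = 1e-12)

  B <- expression_matrix(unclass(random_expression(50, 30, seed = 4)),
                         rownames(G), colnames(G))
  r <- pcc_per_gene(G, B)
  # textbook covariance / (sigma sigma) oracle
  oracle <- numeric(50)
  for (j in 1:50) {
    g <- G[j, , drop = TRUE]; h <- B[j, , drop = TRUE]
    oracle[j] <- mean((g - mean(g)) * (h - mean(h))) /
      (sqrt(mean((g - mean(g))^2)) * sqrt(mean((h - mean(h))^2)))
  }
  expect_equal(as.vector(r), oracle, tolerance = 1e-12)

  v <- unclass(G)
  v[7, ] <- 5  # constant gene
  r2 <- pcc_per_gene(expression_matrix(v, rownames(G), colnames(G)), B)
  expect_equal(as.vector(r2)[7], 0)
  expect_true(attr(r2, "undefined")[7])
  expect_error(pcc_per_gene(G[, 1:2], B[, 1:2]), "3 samples")
})

test_that("permutation test: self-prediction is maximally significant", {
  set.seed(5)
  G <- random_expression(1000, 50, seed = 5)
  res <- permutation_test(G, G, "g500")
  expect_equal(res$p, 0)
  expect_true(res$significant)
  expect_equal(res$r, 1)

  # significance is strict: p < alpha, so alpha = 0 can never be significant
  res2 <- permutation_test(G, G, "g001", alpha = 0)
  expect_false(res2$significant)
  expect_error(permutation_test(G[1, ], G[1, ], 1), "2 genes")
})

test_that("permutation p agrees with a brute-force reference scan", {
  G <- random_expression(50, 30, seed = 6)
  H <- expression_matrix(unclass(G) +
                           matrix(rnorm(50 * 30, sd = 2), 50, 30),
                         rownames(G), colnames(G))
  for (j in c(1, 17, 50)) {
    res <- permutation_test(G, H, j)
    r_self <- cor(G[j, , drop = TRUE], H[j, , drop = TRUE])
    ref <- vapply(setdiff(1:50, j),
                  function(i) cor(G[i, , drop = TRUE], H[j, , drop = TRUE]),
                  numeric(1))
    expect_equal(res$p, mean(ref >= r_self), tolerance = 1e-12)
  }
  # the vectorized all-gene path agrees with the single-gene path
  rep_all <- evaluate_predictions(G, H)
  for (j in c(2, 25)) {
    expect_equal(rep_all$per_gene$perm_p[j], permutation_test(G, H, j)$p,
                 tolerance = 1e-12)
  }
})

test_that("evaluation reports assemble summaries and survive a disk round-trip", {
  G <- random_expression(40, 20, seed = 7)
  H <- expression_matrix(unclass(G) + matrix(rnorm(800, sd = 0.5), 40, 20),
                         rownames(G), colnames(G))
  rep <- evaluate_predictions(G, H, alpha = 0.01)
  expect_equal(nrow(rep$per_gene), 40)
  expect_true(all(rep$per_gene$perm_p >= 0 & rep$per_gene$perm_p <= 1))
  expect_equal(rep$summary$mean_mae, mean(rep$per_gene$mae))
  expect_equal(rep$summary$n_significant, sum(rep$per_gene$significant))
  # constant genes are never significant
  v <- unclass(G); v[3, ] <- 1
  rep2 <- evaluate_predictions(expression_matrix(v, rownames(G), colnames(G)), H)
  expect_false(rep2$per_gene$significant[3])

  path <- tempfile(fileext = ".tsv")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$per_gene$mae, rep$per_gene$mae, tolerance = 1e-12)
  expect_equal(back$summary$mean_pcc, rep$summary$mean_pcc, tolerance = 1e-12)
  unlink(path)
})

test_that("paired set comparison matches t.test and is antisymmetric", {
  G <- random_expression(30, 25, seed = 8)
  mk <- function(sd, seed) {
    set.seed(seed)
    expression_matrix(unclass(G) + matrix(rnorm(750, sd = sd), 30, 25),
                      rownames(G), colnames(G))
  }
  repA <- evaluate_predictions(G, mk(0.3, 1))
  repB <- evaluate_predictions(G, mk(0.8, 2))
  cmp <- compare_landmark_sets(repA, repB)
  tt <- t.test(repA$per_gene$mae, repB$per_gene$mae, paired = TRUE)
  expect_equal(cmp$mae_test$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cmp$mae_test$p, tt$p.value, tolerance = 1e-12)
  expect_lt(cmp$mae_test$t, 0)  # A (less noise) has lower MAE

  swap <- compare_landmark_sets(repB, repA)
  expect_equal(swap$delta_mae, -cmp$delta_mae)
  expect_equal(swap$mae_test$t, -cmp$mae_test$t)
  expect_equal(swap$pcc_test$t, -cmp$pcc_test$t)

  # identical reports: t = 0, p = 1, all-zero deltas
  same <- compare_landmark_sets(repA, repA)
  expect_equal(same$mae_test$t, 0)
  expect_equal(same$mae_test$p, 1)
  expect_true(all(same$delta_mae == 0))
  expect_true(same$mae_test$zero_variance)

  # constant nonzero delta: degenerate, p = 0 with flag
  mk_report <- function(mae) {
    structure(list(per_gene = data.frame(gene_id = paste0("g", 1:10),
                                         mae = mae, pcc = rep(0.5, 10),
                                         stringsAsFactors = FALSE)),
              class = "EvaluationReport")
  }
  deg <- compare_landmark_sets(mk_report(rep(0.5, 10)), mk_report(rep(0.25, 10)))
  expect_equal(deg$mae_test$p, 0)
  expect_true(deg$mae_test$zero_variance)
  expect_equal(deg$delta_mae, rep(0.25, 10))
})

test_that("embedding cluster quality behaves at its extremes", {
  # identical within class, well separated between classes -> ARI 1
  E <- cbind(matrix(0, 5, 10), matrix(10, 5, 10), matrix(-10, 5, 10))
  labels <- rep(c("a", "b", "c"), each = 10)
  q <- embedding_cluster_quality(E, labels, seed = 1)
  expect_equal(q$ari, 1)
  expect_gt(q$silhouette, 0.9)

  # shuffled labels: chance-corrected ARI near 0
  set.seed(2)
  aris <- replicate(20, {
    embedding_cluster_quality(E, sample(labels), seed = 1)$ari
  })
  expect_lt(abs(mean(aris)), 0.1)
  expect_error(embedding_cluster_quality(E, rep("a", 30)), "2 label")
})
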