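test_that("rescale multipliers are finite-difference slopes with gradient fallback", {
  expect_equal(rescale_multiplier(1, 0, "sigmoid"),
               sigmoid(1) - sigmoid(0), tolerance = 1e-12)
  expect_equal(sigmoid(1) - sigmoid(0), 0.23106, tolerance = 1e-5)
  expect_equal(rescale_multiplier(3.7, -1.2, "linear"), 1.0)
  expect_equal(rescale_multiplier(0, 0, "sigmoid"), 0.25)  # sigma'(0)
  # fallback threshold: just inside epsilon uses the derivative
  expect_equal(rescale_multiplier(1e-8, 0, "sigmoid", epsilon = 1e-7), 0.25)
  # vectorized over pre-activations
  x <- c(-2, 0, 1.5)
  expect_equal(rescale_multiplier(x, c(0, 0, 0), "sigmoid"),
               c((sigmoid(-2) - 0.5) / -2, 0.25, (sigmoid(1.5) - 0.5) / 1.5))
  expect_error(rescale_multiplier(1, 0, "relu"), "unknown activation")
})

test_that("contributions vanish at the reference and follow single paths", {
  net <- random_network(6, widths = c(4, 2, 4, 6), seed = 3,
                        activations = rep("sigmoid", 4))
  ref <- reference_input(rep(0.5, 6))
  C0 <- propagate_contributions(net, rep(0.5, 6), ref)
  expect_true(all(C0 == 0))

  # one-layer encoder, single sigmoid unit, W = [w], b = 0, ref = 0:
  # the only contribution is sigma(w x) - sigma(0)
  w <- 1.3
  net1 <- manual_network(list(matrix(w, 1, 1)), list(0), "sigmoid")
  x <- 0.8
  C <- propagate_contributions(net1, x, reference_input(0))
  expect_equal(as.vector(C), sigmoid(w * x) - sigmoid(0), tolerance = 1e-12)
})

test_that("all-linear contributions equal the gradient-times-input oracle", {
  for (seed in 1:5) {
    net <- random_network(8, widths = c(5, 3), seed = seed,
                          activations = c("linear", "linear"))
    set.seed(seed)
    x <- runif(8)
    C <- propagate_contributions(net, x, reference_input(rep(0, 8)))
    grad <- net$layers[[2]]$W %*% net$layers[[1]]$W  # 3 x 8 path products
    expect_equal(C, t(grad) * x, tolerance = 1e-10)
  }
})

test_that("summation-to-delta holds across random networks and inputs", {
  set.seed(99)
  for (rep in 1:25) {
    widths <- c(sample(5:50, 1), sample(2:20, 1))
    net <- random_network(sample(5:40, 1), widths = widths, seed = rep)
    for (i in 1:4) {
      x <- runif(net$input_dim)
      r <- runif(net$input_dim)
      C <- propagate_contributions(net, x, reference_input(r))
      delta <- encode(net, x) - encode(net, r)
      expect_lt(max(abs(colSums(C) - delta) / (1 + abs(delta))), 1e-6)
    }
  }
})

test_that("attribution reads the encoder only", {
  net <- random_network(6, widths = c(4, 2, 4, 6), seed = 8,
                        activations = rep("sigmoid", 4))
  set.seed(8)
  x <- runif(6)
  ref <- reference_input(runif(6))
  C1 <- propagate_contributions(net, x, ref)
  perturbed <- net
  perturbed$layers[[3]]$W <- perturbed$layers[[3]]$W + 100
  perturbed$layers[[4]]$b <- perturbed$layers[[4]]$b - 5
  C2 <- propagate_contributions(perturbed, x, ref)
  expect_identical(C1, C2)
})

test_that("contribution tensors are deterministic and validated", {
  net <- random_network(10, widths = c(5, 3), seed = 4,
                        activations = c("sigmoid", "sigmoid"))
  X <- unit_expression(10, 8, seed = 5)
  ref <- reference_from_training(X)
  C1 <- contribution_tensor(net, X, ref)
  C2 <- contribution_tensor(net, X, ref)
  expect_identical(C1, C2)
  expect_equal(dim(C1), c(8, 10, 3))
  expect_error(propagate_contributions(net, rep(2, 10), ref), "unit scale")

  sub <- contribution_tensor(net, X, ref, n_subsample = 3, seed = 2)
  expect_equal(dim(sub)[1], 3)
  expect_true(all(dimnames(sub)[[1]] %in% colnames(X)))
})

test_that("reference_from_training is the per-gene mean", {
  X <- unit_expression(12, 9, seed = 6)
  ref <- reference_from_training(X)
  expect_equal(ref$source, "train_mean")
  # brute-force column-mean loop
  expected <- numeric(12)
  for (i in 1:12) expected[i] <- sum(X[i, ]) / 9
  expect_equal(ref$values, expected, tolerance = 1e-12)

  const <- expression_matrix(matrix(0.3, 4, 5))
  expect_equal(reference_from_training(const)$values, rep(0.3, 4))
  two <- expression_matrix(cbind(rep(0, 3), rep(1, 3)))
  expect_equal(reference_from_training(two)$values, rep(0.5, 3))
})

test_that("importance aggregation matches a brute-force triple loop", {
  net <- random_network(7, widths = c(4, 2), seed = 10,
                        activations = c("sigmoid", "sigmoid"))
  X <- unit_expression(7, 5, seed = 11)
  C <- contribution_tensor(net, X, reference_from_training(X))
  ranking <- aggregate_importance(C)

  score <- setNames(numeric(7), dimnames(C)[[2]])
  for (s in 1:5) for (i in 1:7) for (t in 1:2) {
    score[i] <- score[i] + abs(C[s, i, t])
  }
  score <- score / (5 * 2)
  expect_equal(setNames(ranking$score, ranking$gene_id),
               score[order(-score, names(score))], tolerance = 1e-12)
  expect_false(is.unsorted(rev(ranking$score)))
})

test_that("a gene fixed at its reference has importance zero and ranks last", {
  net <- random_network(6, widths = c(4, 2), seed = 12,
                        activations = c("sigmoid", "sigmoid"))
  v <- unclass(unit_expression(6, 10, seed = 13))
  v[4, ] <- 0.42   # constant gene equal to its own mean/reference
  X <- expression_matrix(v, gene_ids = sprintf("g%03d", 1:6),
                         sample_ids = sprintf("s%03d", 1:10))
  C <- contribution_tensor(net, X, reference_from_training(X))
  ranking <- aggregate_importance(C)
  expect_identical(ranking$score[ranking$gene_id == "g004"], 0)
  expect_equal(ranking$gene_id[6], "g004")

  # doubling one gene's contributions ranks it above an equal peer
  C2 <- C
  C2[, 2, ] <- 2 * C2[, 1, ]
  C2[, 1, ] <- C2[, 1, ]
  r2 <- aggregate_importance(C2)
  expect_lt(which(r2$gene_id == "g002"), which(r2$gene_id == "g001"))
})

test_that("landmark selection takes the top of the ranking, in order", {
  ranking <- structure(
    data.frame(gene_id = c("c", "a", "b", "d"),
               score = c(4, 3, 2, 1), stringsAsFactors = FALSE),
    class = c("ImportanceRanking", "data.frame"))
  expect_equal(select_landmarks(ranking, 1)$gene_ids, "c")
  expect_equal(select_landmarks(ranking, 4)$gene_ids, c("c", "a", "b", "d"))
  expect_error(select_landmarks(ranking, 5), "between 1 and 4")
  expect_error(select_landmarks(ranking, 0), "between")
  expect_equal(formals(select_landmarks)$k, 943L)
})
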