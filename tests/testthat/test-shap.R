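test_that("brute-force Shapley satisfies the defining axioms on closed forms", {
  # additivity: f(x) = sum(x), all-zero background -> phi_i = x_i
  f_add <- function(Z) rowSums(Z)
  x <- c(1.5, -2, 0.5)
  B <- matrix(0, 4, 3)
  expect_equal(brute_force_shapley(f_add, x, B, 3), x)
  # symmetry: exchangeable features (and background) share credit equally
  f_sym <- function(Z) Z[, 1] * Z[, 2] + Z[, 1] + Z[, 2]
  B2 <- matrix(rnorm(5), 5, 2)  # identical columns keep features exchangeable
  phi <- brute_force_shapley(f_sym, c(0.7, 0.7), B2, 2)
  expect_equal(phi[1], phi[2])
  # product of two binaries, x = (1,1), uniform background over {0,1}^2
  f_prod <- function(Z) Z[, 1] * Z[, 2]
  B3 <- as.matrix(expand.grid(0:1, 0:1))
  expect_equal(brute_force_shapley(f_prod, c(1, 1), B3, 2), c(0.375, 0.375))
  expect_error(brute_force_shapley(f_add, rep(1, 13), matrix(0, 2, 13), 13),
               "small d")
})

test_that("tree SHAP reproduces the single-split and constant closed forms", {
  st <- stump(1, 0, 0, 10, "pos")
  B <- matrix(c(-1, -2, 1, 2), 4, 1)  # half the rows on each side
  res <- tree_shap(st, x = 3, B)
  expect_equal(res$phi[1, 1], 5.0)
  expect_equal(res$base, 5.0)
  ct <- leaf_tree(c(2.5, -1), c("a", "b"))
  res2 <- tree_shap(ct, x = 0, matrix(rnorm(6), 6, 1))
  expect_equal(unname(res2$phi), matrix(0, 1, 2))
  expect_equal(res2$base, c(2.5, -1))
  expect_error(tree_shap(st, 1, matrix(0, 0, 1)), "empty background")
  expect_error(tree_shap(st, c(1, 2), B), "feature-count mismatch")
})

test_that("tree SHAP equals the brute-force oracle on random trees", {
  set.seed(42)
  for (r in 1:12) {
    d <- sample(2:4, 1)
    tr <- rand_tree(d, depth = 3)
    B <- matrix(rnorm(6 * d), 6, d)
    x <- rnorm(d)
    res <- tree_shap(tr, x, B)
    for (ci in 1:2) {
      oracle <- brute_force_shapley(function(Z) predict(tr, Z)[, ci], x, B, d)
      expect_equal(res$phi[, ci], oracle, tolerance = 1e-8)
    }
    fx <- predict(tr, matrix(x, 1))[1, ]
    expect_equal(colSums(res$phi) + res$base, fx, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("constrained sub-ensemble SHAP follows the covariance arithmetic", {
  # stub per-tree attribution: trees with per-feature phi [1,3] and [3,1]
  per_tree <- list(phi = array(c(1, 3, 3, 1), c(2, 1, 2, 1)),
                   base = matrix(0, 2, 1),
                   feature_names = c("x1", "x2"), class_names = "c1")
  ens <- fixture_forest()$ensemble  # only K and classes consulted here
  fake_ens <- structure(list(n_trees = 2, classes = "c1"),
                        class = "ensemble_view")
  adj <- constrained_treeshap(c(1L, 2L), fake_ens, matrix(0, 1, 2),
                              matrix(0, 1, 2), per_tree = per_tree)
  expect_equal(adj$phi_mean[1, , 1], c(2, 2))
  expect_equal(adj$sigma_diag[1, , 1], c(1, 1))  # population convention
  expect_equal(adj$phi_adj[1, , 1], c(2.5, 2.5))
  # same tree twice: zero covariance, phi_adj collapses to the tree's phi
  adj2 <- constrained_treeshap(c(2L, 2L), fake_ens, matrix(0, 1, 2),
                               matrix(0, 1, 2), per_tree = per_tree)
  expect_equal(adj2$phi_adj[1, , 1], c(3, 1))
  expect_equal(adj2$Sigma[, , 1, 1], matrix(0, 2, 2))
  # adjustment adds half a variance: never below the mean
  expect_true(all(adj$phi_adj >= adj$phi_mean))
})

test_that("sub-ensemble SHAP preserves local accuracy on a real forest", {
  sf <- small_forest_fit()
  ens <- sf$ensemble
  X <- as.matrix(sf$data$X[1:5, ])
  B <- as.matrix(sf$data$X[1:40, ])
  sub <- c(1L, 4L, 4L, 9L)
  adj <- constrained_treeshap(sub, ens, X, B)
  pred <- predict(ens, X, trees = sub)
  for (ci in seq_along(ens$classes))
    expect_equal(rowSums(adj$phi_mean[, , ci]) + adj$base_mean[, ci],
                 pred[, ci], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("features unused by a sub-ensemble get exactly zero attribution", {
  classes <- "c1"
  t1 <- stump(1, 0, 0, 4, classes)
  t2 <- stump(1, 1, -1, 2, classes)
  ens <- ensemble_view(list(t1, t2), classes)
  X <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(15), 5, 3)
  adj <- constrained_treeshap(c(1L, 2L), ens, X, B)
  expect_equal(adj$phi_mean[, 2:3, 1], matrix(0, 3, 2))
  expect_equal(adj$sigma_diag[, 2:3, 1], matrix(0, 3, 2))
})

test_that("the SHAP tensor indexes per-tree values by hypothesis sample", {
  sf <- small_forest_fit()
  ens <- sf$ensemble
  X <- as.matrix(sf$data$X[1:3, ])
  B <- as.matrix(sf$data$X[1:30, ])
  per_tree <- per_tree_shap(ens, X, B)
  w <- rep(1 / ens$n_trees, ens$n_trees)
  samples <- dirichlet_sample(w, sampling_config(n_samples = 4, n_draw = 5,
                                                 seed = 2))
  tens <- shap_tensor(samples, per_tree)
  arr <- as.array(tens)
  expect_equal(dim(arr), c(4L, 5L, 3L, 6L, 3L))
  bv <- base_values(tens)
  # local accuracy holds cell-by-cell: each slot is one tree's exact SHAP
  for (s in 1:4) for (t in 1:5) {
    k <- samples[[s]]$tree_indices[t]
    pred <- predict(ens$trees[[k]], X)
    for (ci in 1:3)
      expect_equal(rowSums(arr[s, t, , , ci]) + bv[s, t, ci], pred[, ci],
                   tolerance = 1e-6, ignore_attr = TRUE)
  }
})
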