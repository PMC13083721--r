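test_that("out-of-bag accuracy matches exhaustive counting on the fixture forest", {
  fx <- fixture_forest()
  a <- compute_per_tree_oob_accuracy(fx$ensemble, fx$X, fx$y)
  # tree 1: OOB rows 6:10 all labeled b and predicted b -> perfect
  expect_equal(a[1], 1.0)
  # tree 2: constant class-a predictor on an OOB set where a is 40% of rows
  expect_equal(a[2], 0.4)
})

test_that("all-in-bag masks trigger the full-data fallback with a warning", {
  fx <- fixture_forest()
  ens <- ensemble_view(fx$ensemble$trees, fx$ensemble$classes,
                       matrix(TRUE, 10, 2))
  expect_warning(a <- compute_per_tree_oob_accuracy(ens, fx$X, fx$y),
                 "empty out-of-bag")
  expect_equal(a, c(0.9, 0.4))  # full-data accuracies, counted by hand
})

test_that("missing masks require a held-out set and empty data errors", {
  fx <- fixture_forest()
  ens <- ensemble_view(fx$ensemble$trees, fx$ensemble$classes)
  expect_error(compute_per_tree_oob_accuracy(ens, fx$X, fx$y), "held-out")
  a <- compute_per_tree_oob_accuracy(ens, NULL, NULL,
                                     holdout = list(X = fx$X, y = fx$y))
  expect_equal(a, c(0.9, 0.4))
  expect_error(
    compute_per_tree_oob_accuracy(ens, NULL, NULL,
                                  holdout = list(X = fx$X[0, , drop = FALSE],
                                                 y = character(0))),
    "no evaluation data")
})

test_that("argmax classification breaks ties toward the lowest class index", {
  classes <- c("a", "b")
  tie_tree <- leaf_tree(c(0.5, 0.5), classes)
  ens <- ensemble_view(list(tie_tree, tie_tree), classes,
                       matrix(FALSE, 4, 2))
  a <- compute_per_tree_oob_accuracy(ens, data.frame(x1 = 1:4),
                                     c("a", "a", "b", "b"))
  expect_equal(a, c(0.5, 0.5))  # always predicts "a"
})

test_that("softmax weights reproduce the hand examples", {
  expect_equal(softmax_weights(c(0.7, 0.7, 0.7), 5), rep(1 / 3, 3))
  expect_equal(softmax_weights(c(0.2, 0.9, 0.4), 0), rep(1 / 3, 3))
  w <- softmax_weights(c(0.9, 0.8), 5)
  expect_equal(w, c(plogis(0.5), 1 - plogis(0.5)))
  expect_equal(round(w, 4), c(0.6225, 0.3775))
})

test_that("softmax weights are monotone, translation-invariant, and simplex", {
  set.seed(1)
  for (r in 1:20) {
    a <- runif(6)
    beta <- runif(1, 0.5, 10)
    w <- softmax_weights(a, beta)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    ord <- order(a)
    expect_equal(order(w), ord)  # a_i > a_j => w_i > w_j
    expect_equal(softmax_weights(a + 17.3, beta), w, tolerance = 1e-12)
  }
  expect_error(softmax_weights(c(0.5, NA), 2), "non-finite")
  expect_error(softmax_weights(c(0.5, 0.6), -1), "nonnegative")
})

test_that("ranger forests convert to tree views with matching predictions", {
  sf <- small_forest_fit()
  ds <- sf$data
  ens <- sf$ensemble
  rf <- ranger::ranger(x = ds$X, y = ds$y, num.trees = 12,
                       probability = TRUE, keep.inbag = TRUE,
                       max.depth = 4, seed = 5, num.threads = 1)
  pa <- predict(rf, ds$X, predict.all = TRUE, num.threads = 1)$predictions
  for (k in c(1, 5, 12)) {
    mine <- predict(ens$trees[[k]], ds$X)
    expect_equal(unname(mine), unname(pa[, , k]), tolerance = 1e-10)
  }
  expect_equal(dim(ens$bootstrap_masks), c(300L, 12L))
})

test_that("JSON tree-dump round-trips an ensemble exactly", {
  fx <- fixture_forest()
  tmp <- tempfile(fileext = ".json")
  write_tree_dump(fx$ensemble, tmp)
  back <- read_tree_dump(tmp)
  expect_equal(back$classes, fx$ensemble$classes)
  expect_equal(back$bootstrap_masks, fx$ensemble$bootstrap_masks)
  X <- data.frame(x1 = seq(0, 11, by = 0.5))
  for (k in 1:2)
    expect_equal(predict(back$trees[[k]], X),
                 predict(fx$ensemble$trees[[k]], X))
})

test_that("malformed node tables are rejected with the offending node", {
  expect_error(tree_view(feature = c(1, NA, NA), threshold = c(NA, NA, NA),
                         left = c(2, NA, NA), right = c(3, NA, NA),
                         values = rbind(0, 0, 1), classes = "c1"),
               "node 1")
  expect_error(make_fixture_forest(list(
    trees = list(data.frame(feature = c(1, NA, NA), threshold = c(0, NA, NA),
                            left = c(2, NA, NA), right = c(9, NA, NA),
                            leaf_a = c(0, 0, 1))),
    classes = "a")), "child outside")
})
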