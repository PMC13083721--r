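test_that("generation is deterministic per seed and distinct across seeds", {
  cfg <- scenario_config(n_rows = 200, seed = 9)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- make_dataset(scenario_config(n_rows = 200, seed = 10))
  expect_false(identical(d1$X, d3$X))
})

test_that("with no informative features class proportions follow the ratios", {
  cfg <- scenario_config(n_rows = 3000, informative = integer(0),
                         coefficients = numeric(0), n_classes = 3,
                         class_ratios = c(0.5, 0.3, 0.2), seed = 4)
  ds <- make_dataset(cfg)
  prop <- as.numeric(table(ds$y)) / 3000
  se <- sqrt(c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8) / 3000)
  expect_true(all(abs(prop - c(0.5, 0.3, 0.2)) < 3 * se))
})

test_that("duplicate-feature maps copy columns exactly", {
  cfg <- scenario_config(n_rows = 100, duplicate_map = c("5" = 1), seed = 2)
  ds <- make_dataset(cfg)
  expect_identical(ds$X$x5, ds$X$x1)
})

test_that("a noiseless strong-signal dataset is nearly separable by a forest", {
  ds <- make_dataset(scenario_config(n_rows = 600, label_noise = 0, seed = 12))
  rf <- ranger::ranger(x = ds$X, y = ds$y, num.trees = 40,
                       probability = TRUE, min.node.size = 1, seed = 1,
                       num.threads = 1)
  pred <- predict(rf, ds$X, num.threads = 1)$predictions
  acc <- mean(levels(ds$y)[max.col(pred)] == as.character(ds$y))
  expect_gte(acc, 0.99)
})

test_that("categorical features are emitted as integer codes with recorded effects", {
  cfg <- scenario_config(n_rows = 400, n_features = 5, informative = c(1, 3),
                         coefficients = c(2, 2),
                         categorical = c("3" = 4), seed = 6)
  ds <- make_dataset(cfg)
  expect_true(all(ds$X$x3 %in% 0:3))
  expect_true("3" %in% names(ds$truth$categorical_effects))
  expect_equal(dim(ds$truth$categorical_effects[["3"]]), c(4L, 3L))
})

test_that("infeasible imbalance is rejected", {
  cfg <- scenario_config(n_rows = 20, n_classes = 4,
                         class_ratios = c(0.9, 0.06, 0.03, 0.01), seed = 1)
  expect_error(make_dataset(cfg), "infeasible imbalance")
})

test_that("the preset suite covers the documented scenarios reproducibly", {
  suite <- scenario_suite(seed = 1)
  expect_gte(length(suite), 5)
  expect_equal(suite$imbalance$class_ratios, c(0.60, 0.20, 0.15, 0.05))
  expect_equal(vapply(suite[paste0("noise_", c("000", "010", "020", "030"))],
                      `[[`, 1, "label_noise"),
               c(noise_000 = 0, noise_010 = 0.1, noise_020 = 0.2,
                 noise_030 = 0.3))
  expect_equal(suite$collinearity$duplicate_map, c("5" = 1))
  for (nm in names(suite))
    expect_identical(make_dataset(suite[[nm]])$X,
                     make_dataset(scenario_suite(seed = 1)[[nm]])$X)
})

test_that("fixture forests expose closed-form predictions and OOB sets", {
  fx <- fixture_forest()
  expect_equal(predict(fx$ensemble$trees[[1]],
                       data.frame(x1 = c(2, 8)))[, "a"], c(1, 0))
  # single-leaf trees carry zero SHAP everywhere
  res <- tree_shap(fx$ensemble$trees[[2]], x = 3, matrix(1:4, 4, 1))
  expect_equal(unname(res$phi), matrix(0, 1, 2))
  # identical trees produce zero epistemic variance across sub-ensembles
  per_tree <- per_tree_shap(fx$ensemble, matrix(c(2, 8), 2, 1),
                            matrix(1:10, 10, 1), trees = c(1L, 1L))
  samples <- list(
    structure(list(pi = c(1, 0), tree_indices = c(1L, 1L), sample_id = 1,
                   seed_state = 0), class = "hypothesis_sample"),
    structure(list(pi = c(1, 0), tree_indices = c(1L, 1L), sample_id = 2,
                   seed_state = 0), class = "hypothesis_sample"))
  by_sample <- lapply(samples, function(s)
    per_tree$phi[s$tree_indices, 1, , 1])
  d <- decompose_variance(by_sample)
  expect_equal(d$epistemic, 0)
})

test_that("informative features dominate noise features in mean |SHAP|", {
  ds <- make_dataset(scenario_config(n_rows = 400, seed = 31))
  fit <- ubiqtree(y ~ ., cbind(ds$X, y = ds$y), n_trees = 30, n_samples = 10,
                  n_explain = 30, n_background = 64, seed = 31)
  imp <- rowMeans(vapply(fit$classes, function(cl)
    colMeans(abs(fit$mu_s[, , cl])), numeric(10)))
  expect_gt(mean(imp[1:4]), max(imp[5:10]))
})
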