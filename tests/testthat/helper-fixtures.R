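# Hand-built fixtures shared across the suite. Everything is generated in
# code; per-tree predictions and OOB sets are known in closed form.

# random binary-class tree with depth <= `depth` over d features
rand_tree <- function(d, depth = 3, n_classes = 2) {
  nodes <- list()
  build <- function(dep) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()
    if (dep >= depth || stats::runif(1) < 0.3) {
      nodes[[id]] <<- list(feature = NA, threshold = NA, left = NA,
                           right = NA, value = stats::rnorm(n_classes))
      return(id)
    }
    f <- sample.int(d, 1); t <- stats::rnorm(1)
    l <- build(dep + 1); r <- build(dep + 1)
    nodes[[id]] <<- list(feature = f, threshold = t, left = l, right = r,
                         value = rep(0, n_classes))
    id
  }
  build(0)
  tree_view(sapply(nodes, `[[`, "feature"),
            sapply(nodes, `[[`, "threshold"),
            sapply(nodes, `[[`, "left"),
            sapply(nodes, `[[`, "right"),
            t(sapply(nodes, `[[`, "value")),
            paste0("c", seq_len(n_classes)))
}

# a stump on one feature with the two leaf score vectors given
stump <- function(feature, threshold, left_value, right_value, classes) {
  tree_view(feature = c(feature, NA, NA), threshold = c(threshold, NA, NA),
            left = c(2, NA, NA), right = c(3, NA, NA),
            values = rbind(rep(0, length(classes)), left_value, right_value),
            classes = classes)
}

# single constant leaf
leaf_tree <- function(value, classes) {
  tree_view(NA, NA, NA, NA, matrix(value, 1), classes)
}

# 10-row two-class fixture: x1 = 1..10, labels a for x1 <= 4, b otherwise.
# Tree 1 splits at 5 (classifies rows 5 wrong only), tree 2 is the constant
# class-a predictor. Masks: tree 1 in-bag rows 1:5, tree 2 in-bag none.
fixture_forest <- function() {
  classes <- c("a", "b")
  t1 <- stump(1, 5, c(1, 0), c(0, 1), classes)
  t2 <- leaf_tree(c(1, 0), classes)
  masks <- cbind(rep(c(TRUE, FALSE), each = 5), rep(FALSE, 10))
  X <- data.frame(x1 = 1:10)
  y <- c(rep("a", 4), rep("b", 6))
  list(ensemble = ensemble_view(list(t1, t2), classes, masks), X = X, y = y)
}

# small trained forest reused by several files (cached per session)
small_forest_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_dataset(scenario_config(n_rows = 300, n_features = 6,
                                         informative = 1:2,
                                         coefficients = c(2.5, 2),
                                         seed = 5))
      rf <- ranger::ranger(x = ds$X, y = ds$y, num.trees = 12,
                           probability = TRUE, keep.inbag = TRUE,
                           max.depth = 4, seed = 5, num.threads = 1)
      cache <<- list(ensemble = as_ensemble_view(rf), data = ds)
    }
    cache
  }
})
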