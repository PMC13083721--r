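#' Scenario configuration for the synthetic tabular generator
#'
#' Describes a multiclass tabular classification scenario with known ground
#' truth: which features carry signal, how strongly, how noisy the labels
#' are, and how imbalanced the classes. The generator emulates clinical
#' risk-class tabular data (mixed numeric and label-encoded categorical
#' features, i.i.d. rows).
#'
#' @param n_rows number of rows.
#' @param n_features total feature count `d`.
#' @param informative integer indices of signal-carrying features.
#' @param coefficients positive effect sizes, one per informative feature
#'   (logit scale).
#' @param n_classes number of classes (>= 2).
#' @param class_ratios marginal class proportions (sum to 1).
#' @param label_noise probability in `[0, 0.5)` that a label is replaced by
#'   a uniformly chosen different class.
#' @param categorical named integer vector: `categorical["3"] = 4` makes
#'   feature 3 a 4-level categorical emitted as integer codes `0..3`.
#' @param duplicate_map named integer vector: `duplicate_map["5"] = 1`
#'   copies feature 1 into feature 5 (exact collinearity scenarios).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_rows = 1000, n_features = 10,
                            informative = 1:4,
                            coefficients = 1.8 * c(1.6, 1.3, 1.0, 0.8),
                            n_classes = 3,
                            class_ratios = rep(1 / n_classes, n_classes),
                            label_noise = 0, categorical = NULL,
                            duplicate_map = NULL, seed = 1) {
  stopifnot(n_rows >= 10, n_features >= 1, n_classes >= 2)
  if (length(informative) &&
      (any(informative < 1) || any(informative > n_features)))
    stop("informative set must be within the feature indices")
  if (length(coefficients) != length(informative))
    stop("one coefficient per informative feature")
  if (abs(sum(class_ratios) - 1) > 1e-8)
    stop("class ratios must sum to 1")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5)")
  structure(list(n_rows = as.integer(n_rows),
                 n_features = as.integer(n_features),
                 informative = as.integer(informative),
                 coefficients = as.numeric(coefficients),
                 n_classes = as.integer(n_classes),
                 class_ratios = as.numeric(class_ratios),
                 label_noise = label_noise,
                 categorical = categorical, duplicate_map = duplicate_map,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a synthetic multiclass tabular dataset with known truth
#'
#' Numeric features are standard normal; categorical features are uniform
#' integer codes. Labels are drawn from a softmax of sparse linear logits:
#' each informative numeric feature pushes one class up (its coefficient)
#' and the others down (zero-sum loading); informative categoricals act
#' through fixed per-level effects. Class intercepts are the log ratios, so
#' with no informative features the class proportions match `class_ratios`.
#' Finally, labels are flipped to a uniformly chosen other class at rate
#' `label_noise`.
#'
#' @param cfg a [scenario_config()].
#' @return List with `X` (data frame, columns `x1..xd`), `y` (factor with
#'   levels `c1..cK`), and `truth` (coefficient matrix on the logit scale,
#'   informative set, noise rate, per-level categorical effects, level maps,
#'   seed).
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (any(cfg$n_rows * cfg$class_ratios < 1))
    stop("infeasible imbalance: a class has expected count below 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  d <- cfg$n_features; n <- cfg$n_rows; C <- cfg$n_classes
  cat_idx <- if (is.null(cfg$categorical)) integer(0)
             else as.integer(names(cfg$categorical))
  X <- matrix(0, n, d)
  for (j in seq_len(d)) {
    X[, j] <- if (j %in% cat_idx)
      sample.int(cfg$categorical[[as.character(j)]], n, replace = TRUE) - 1
    else stats::rnorm(n)
  }
  # zero-sum per-class loadings: informative feature i pushes class axis(i)
  Bmat <- matrix(0, d, C)
  cat_effects <- list()
  for (ii in seq_along(cfg$informative)) {
    j <- cfg$informative[ii]; cf <- cfg$coefficients[ii]
    ax <- (ii - 1) %% C + 1
    if (j %in% cat_idx) {
      L <- cfg$categorical[[as.character(j)]]
      eff <- matrix(stats::rnorm(L * C, sd = cf), L, C)
      eff <- eff - rowMeans(eff)
      cat_effects[[as.character(j)]] <- eff
    } else {
      Bmat[j, ] <- -cf / (C - 1)
      Bmat[j, ax] <- cf
    }
  }
  logits <- X %*% Bmat
  for (j in names(cat_effects))
    logits <- logits + cat_effects[[j]][X[, as.integer(j)] + 1, , drop = FALSE]
  logits <- sweep(logits, 2, log(cfg$class_ratios), "+")
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  y <- vapply(seq_len(n), function(i)
    sample.int(C, 1, prob = P[i, ]), 1L)
  flip <- stats::runif(n) < cfg$label_noise
  if (any(flip))
    y[flip] <- vapply(y[flip], function(cl)
      sample(setdiff(seq_len(C), cl), 1L), 1L)
  if (!is.null(cfg$duplicate_map))
    for (tgt in names(cfg$duplicate_map))
      X[, as.integer(tgt)] <- X[, cfg$duplicate_map[[tgt]]]
  Xdf <- as.data.frame(X)
  names(Xdf) <- paste0("x", seq_len(d))
  list(X = Xdf,
       y = factor(paste0("c", y), levels = paste0("c", seq_len(C))),
       truth = list(coefficients = Bmat, informative = cfg$informative,
                    label_noise = cfg$label_noise,
                    categorical_effects = cat_effects,
                    categorical_levels = cfg$categorical,
                    class_ratios = cfg$class_ratios, seed = cfg$seed))
}

#' Hand-built fixture forest from node tables
#'
#' Builds an [ensemble_view] whose per-tree predictions and out-of-bag sets
#' are known in closed form — the oracle scaffolding used throughout the
#' test suite.
#'
#' @param spec list with `trees` (list of node tables: data frames with
#'   columns `feature`, `threshold`, `left`, `right`, plus one `leaf_*`
#'   column per class), `classes`, and optional `masks` (logical matrix,
#'   rows x trees).
#' @return An `ensemble_view`.
#' @export
make_fixture_forest <- function(spec) {
  trees <- lapply(spec$trees, function(nt) {
    vcols <- grep("^leaf_", names(nt), value = TRUE)
    if (!length(vcols)) stop("node table lacks leaf_* value columns")
    tree_view(nt$feature, nt$threshold, nt$left, nt$right,
              as.matrix(nt[, vcols, drop = FALSE]), spec$classes)
  })
  ensemble_view(trees, spec$classes, spec$masks)
}

#' Named scenario presets
#'
#' The study conditions every pipeline property is probed under:
#' \describe{
#'   \item{baseline}{n = 1000, d = 10, 4 informative features, 3 balanced
#'     classes, no label noise; logit scale tuned so the Bayes accuracy is
#'     about 0.85.}
#'   \item{noise_000 .. noise_030}{label-noise sweep 0, 0.1, 0.2, 0.3.}
#'   \item{n_200, n_500, n_2000}{sample-size sweep.}
#'   \item{imbalance}{four classes at 60/20/15/5.}
#'   \item{collinearity}{feature 5 duplicates feature 1 exactly.}
#' }
#'
#' @param seed base seed stamped into every preset.
#' @return Named list of [scenario_config()] objects.
#' @export
scenario_suite <- function(seed = 1) {
  base <- function(...) scenario_config(seed = seed, ...)
  noise <- c(0, 0.1, 0.2, 0.3)
  presets <- c(
    list(baseline = base()),
    stats::setNames(lapply(noise, function(r) base(label_noise = r)),
                    sprintf("noise_%03d", round(noise * 100))),
    stats::setNames(lapply(c(200, 500, 2000), function(n) base(n_rows = n)),
                    paste0("n_", c(200, 500, 2000))),
    list(imbalance = base(n_classes = 4,
                          class_ratios = c(0.60, 0.20, 0.15, 0.05)),
         collinearity = base(duplicate_map = c("5" = 1)))
  )
  presets
}
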