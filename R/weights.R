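#' Per-tree out-of-bag accuracy
#'
#' Each tree of a bagged ensemble is scored on the training rows it did not
#' see (its out-of-bag set): the fraction of those rows whose argmax class
#' matches the label. Ties in the argmax resolve to the lowest class index.
#' These accuracies feed the softmax base measure of the hypothesis sampler.
#'
#' @param ensemble an [ensemble_view] carrying `bootstrap_masks`, or any
#'   object accepted by [as_ensemble_view()].
#' @param X feature data (rows aligned with the masks when masks are used).
#' @param y label vector (factor or character), aligned with `X`.
#' @param holdout optional list `list(X =, y =)`; when the ensemble has no
#'   bootstrap masks every tree is scored on this held-out set instead.
#' @param score `"accuracy"` (default) or `"auc"` for mean one-vs-rest AUC of
#'   the tree's class scores.
#' @return Numeric vector of length K in `[0, 1]`. Trees with an empty OOB
#'   set fall back to the full `(X, y)` and a warning records their indices.
#' @export
compute_per_tree_oob_accuracy <- function(ensemble, X, y, holdout = NULL,
                                          score = c("accuracy", "auc")) {
  score <- match.arg(score)
  ensemble <- as_ensemble_view(ensemble)
  if (is.null(ensemble$bootstrap_masks) && !is.null(holdout)) {
    X <- holdout$X; y <- holdout$y
    masks <- matrix(FALSE, NROW(X), ensemble$n_trees)  # everything held out
  } else if (!is.null(ensemble$bootstrap_masks)) {
    masks <- ensemble$bootstrap_masks
  } else {
    stop("ensemble has no bootstrap masks; supply a held-out set via `holdout`")
  }
  if (NROW(X) == 0L) stop("no evaluation data")
  y <- as.character(y)
  if (NROW(X) != length(y)) stop("X and y lengths differ")
  X <- as.matrix(X)
  fallback <- integer(0)
  a <- vapply(seq_len(ensemble$n_trees), function(k) {
    oob <- which(!masks[, k])
    if (!length(oob)) { fallback <<- c(fallback, k); oob <- seq_len(nrow(X)) }
    sc <- predict(ensemble$trees[[k]], X[oob, , drop = FALSE])
    .tree_score(sc, y[oob], ensemble$classes, score)
  }, 1)
  if (length(fallback))
    warning("tree(s) ", paste(fallback, collapse = ", "),
            " had an empty out-of-bag set; scored on the full data instead")
  a
}

.tree_score <- function(sc, y_true, classes, score) {
  if (score == "accuracy") {
    pred <- classes[max.col(sc, ties.method = "first")]
    return(mean(pred == y_true))
  }
  # mean one-vs-rest AUC over classes present in y_true
  aucs <- vapply(seq_along(classes), function(c) {
    pos <- y_true == classes[c]
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(sc[, c])
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, 1)
  mean(aucs, na.rm = TRUE)
}

#' Softmax weights over per-tree scores
#'
#' Maps per-tree accuracies onto the probability simplex via
#' `w_k = exp(beta * a_k) / sum_j exp(beta * a_j)`, computed with
#' max-subtraction for numerical stability. `beta = 0` gives uniform weights;
#' larger `beta` concentrates weight on the most accurate trees. The weights
#' are invariant to adding a constant to every accuracy.
#'
#' @param a numeric vector of per-tree scores (finite).
#' @param beta nonnegative temperature.
#' @return Numeric simplex vector (sums to 1, all entries positive).
#' @examples
#' softmax_weights(c(0.9, 0.8), beta = 5)   # ~ c(0.622, 0.378)
#' @export
softmax_weights <- function(a, beta) {
  if (!length(a)) stop("empty accuracy vector")
  if (any(!is.finite(a))) stop("non-finite accuracy")
  if (!is.finite(beta) || beta < 0) stop("beta must be a nonnegative real")
  z <- beta * (a - max(a))
  e <- exp(z)
  e / sum(e)
}
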