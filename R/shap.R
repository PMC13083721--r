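#' Exact interventional SHAP values for a single decision tree
#'
#' Computes interventional (background-marginalized) Shapley values of the
#' tree's per-class score for one instance. The value function is
#' `v(S) = mean over background rows b of f(x_S, b_{-S})`: features in the
#' coalition take the instance's values, the rest take the background row's.
#' For a decision tree this is exact and fast: each leaf is reached under a
#' coalition iff every deciding feature on its path takes the right source,
#' and the Shapley weights over the free features collapse to a closed form
#' in the counts of "must-be-present" and "must-be-absent" features.
#'
#' Satisfies local accuracy: `sum(phi) + base = f(x)` per class, with
#' `base = mean over background rows of f(b)`.
#'
#' @param tree a [tree_view].
#' @param x a single instance (numeric vector or 1-row data frame).
#' @param B background matrix/data frame (non-empty, same feature space).
#' @param n_features number of features; defaults to `ncol(B)`.
#' @return List with `phi` (features x classes matrix) and `base`
#'   (per-class numeric vector).
#' @seealso [brute_force_shapley()], the subset-enumeration oracle this
#'   implementation is tested against.
#' @export
tree_shap <- function(tree, x, B, n_features = NULL) {
  B <- as.matrix(B)
  if (nrow(B) == 0L) stop("empty background")
  x <- as.numeric(x)
  d <- if (is.null(n_features)) ncol(B) else n_features
  if (length(x) != ncol(B)) stop("feature-count mismatch between x and B")
  C <- length(tree$classes)
  nb <- nrow(B)
  phi <- matrix(0, d, C)
  fx <- 0     # f(x): sum of leaves reachable with all features from x
  fb <- rep(0, C)  # accumulated v(empty) = mean_b f(b)
  for (lf in tree$leaves) {
    u <- lf$used
    v <- lf$value
    if (!length(u)) { # constant region: every background row reaches it
      fx <- fx + v
      fb <- fb + v * nb
      next
    }
    x_ok <- x[u] > lf$lo & x[u] <= lf$hi
    # b_ok: nb x |u| matrix
    b_ok <- t(t(B[, u, drop = FALSE]) > lf$lo & t(B[, u, drop = FALSE]) <= lf$hi)
    if (all(x_ok)) fx <- fx + v
    need_in  <- x_ok & !t(b_ok)   # |u| x nb: feature must join the coalition
    need_out <- !x_ok & t(b_ok)   # feature must stay out
    dead     <- !x_ok & !t(b_ok)  # leaf unreachable for this background row
    alive <- colSums(dead) == 0L
    if (!any(alive)) next
    p_cnt <- colSums(need_in)[alive]
    n_cnt <- colSums(need_out)[alive]
    # rows reaching the leaf with the empty coalition contribute to the base
    base_rows <- p_cnt == 0L
    if (any(base_rows)) fb <- fb + v * sum(base_rows)
    w_in  <- exp(lgamma(pmax(p_cnt, 1)) + lgamma(n_cnt + 1) -
                 lgamma(p_cnt + n_cnt + 1))
    w_out <- exp(lgamma(p_cnt + 1) + lgamma(pmax(n_cnt, 1)) -
                 lgamma(p_cnt + n_cnt + 1))
    ni <- need_in[, alive, drop = FALSE]
    no <- need_out[, alive, drop = FALSE]
    for (j in seq_along(u)) {
      pos <- sum(w_in[ni[j, ]])
      neg <- sum(w_out[no[j, ]])
      if (pos != 0 || neg != 0)
        phi[u[j], ] <- phi[u[j], ] + v * (pos - neg)
    }
  }
  list(phi = phi / nb, base = fb / nb)
}

#' Brute-force Shapley values by subset enumeration
#'
#' The independent oracle: enumerates all `2^d` coalitions and applies the
#' defining Shapley weighted average under the same interventional value
#' function as [tree_shap()]. Limited to `d <= 12` features.
#'
#' @param f black-box function: matrix of instances -> numeric score vector.
#' @param x single instance (numeric vector).
#' @param B background matrix.
#' @param d number of features.
#' @return Numeric vector of d Shapley values; they sum to
#'   `f(x) - mean(f(B))`.
#' @export
brute_force_shapley <- function(f, x, B, d) {
  if (d > 12) stop("oracle limited to small d (<= 12)")
  B <- as.matrix(B)
  x <- as.numeric(x)
  nb <- nrow(B)
  nsub <- 2^d
  vS <- numeric(nsub)
  members <- vector("list", nsub)
  for (s in seq_len(nsub)) {
    bits <- which(bitwAnd(s - 1L, bitwShiftL(1L, 0:(d - 1))) != 0L)
    members[[s]] <- bits
    Z <- B
    if (length(bits)) Z[, bits] <- matrix(x[bits], nb, length(bits), byrow = TRUE)
    vS[s] <- mean(f(Z))
  }
  phi <- numeric(d)
  fact <- factorial(0:d)
  for (s in seq_len(nsub)) {
    bits <- members[[s]]
    ssize <- length(bits)
    w <- fact[ssize + 1] * fact[d - ssize] / fact[d + 1]
    for (i in setdiff(seq_len(d), bits)) {
      s_with <- s + bitwShiftL(1L, i - 1L)
      phi[i] <- phi[i] + w * (vS[s_with] - vS[s])
    }
  }
  phi
}

#' Sub-ensemble SHAP with between-tree covariance adjustment
#'
#' For each instance and class: per-tree SHAP vectors are computed for every
#' tree slot of the hypothesis sample (a tree drawn twice counts twice),
#' their mean `phi_mean` and between-tree feature covariance `Sigma`
#' (population convention) are formed, and the interaction-adjusted
#' attribution `phi_adj = phi_mean + 0.5 * diag(Sigma)` is reported
#' alongside. `phi_adj` deliberately breaks local accuracy and is never used
#' by the variance decomposition, which consumes the raw per-tree values.
#'
#' @param sub a `hypothesis_sample` (or plain integer vector of tree indices).
#' @param ensemble an [ensemble_view].
#' @param X instance matrix/data frame (rows to explain).
#' @param B background matrix.
#' @param per_tree optional precomputed output of [per_tree_shap()] for this
#'   ensemble/X/B, to avoid recomputation across many samples.
#' @return An `adjusted_shap` object: arrays `phi_mean`, `phi_adj`,
#'   `sigma_diag` of shape (instance, feature, class); `Sigma` of shape
#'   (feature, feature, instance, class); `phi_tree` of shape
#'   (slot, instance, feature, class); `base_mean` (instance x class).
#' @export
constrained_treeshap <- function(sub, ensemble, X, B, per_tree = NULL) {
  idx <- if (inherits(sub, "hypothesis_sample")) sub$tree_indices
         else as.integer(sub)
  if (any(idx < 1L | idx > ensemble$n_trees)) stop("invalid tree index")
  if (NROW(X) == 0L) stop("no instances to explain")
  if (is.null(per_tree)) per_tree <- per_tree_shap(ensemble, X, B, unique(idx))
  n <- dim(per_tree$phi)[2]; d <- dim(per_tree$phi)[3]
  C <- dim(per_tree$phi)[4]
  Tn <- length(idx)
  phi_tree <- per_tree$phi[idx, , , , drop = FALSE]
  phi_mean <- colMeans(phi_tree, dims = 1)  # n x d x C
  sigma_diag <- array(0, c(n, d, C))
  Sigma <- array(0, c(d, d, n, C))
  if (Tn > 1L) {
    for (ci in seq_len(C)) for (ni in seq_len(n)) {
      M <- phi_tree[, ni, , ci]
      dim(M) <- c(Tn, d)
      Mc <- sweep(M, 2, colMeans(M))
      S <- crossprod(Mc) / Tn           # population covariance
      Sigma[, , ni, ci] <- S
      sigma_diag[ni, , ci] <- diag(S)
    }
  }
  base_tree <- per_tree$base[idx, , drop = FALSE]
  structure(list(
    phi_mean = phi_mean,
    phi_adj = phi_mean + 0.5 * sigma_diag,
    sigma_diag = sigma_diag, Sigma = Sigma,
    phi_tree = phi_tree,
    base_mean = matrix(colMeans(base_tree), n, C, byrow = TRUE,
                       dimnames = list(NULL, ensemble$classes)),
    tree_indices = idx, classes = ensemble$classes),
    class = "adjusted_shap")
}

#' Per-tree SHAP values over an instance set
#'
#' Computes [tree_shap()] for each requested tree and instance once; the
#' result is indexed by hypothesis samples to assemble sub-ensemble SHAP
#' without recomputation (the same physical tree appears in many samples).
#'
#' @param ensemble an [ensemble_view].
#' @param X instances to explain.
#' @param B background matrix.
#' @param trees integer vector of tree indices to compute (default: all).
#' @return List with `phi` array (tree, instance, feature, class) — entries
#'   for trees not requested stay zero — and `base` matrix (tree, class).
#' @export
per_tree_shap <- function(ensemble, X, B, trees = seq_len(ensemble$n_trees)) {
  X <- as.matrix(X); B <- as.matrix(B)
  n <- nrow(X); d <- ncol(X); C <- length(ensemble$classes)
  phi <- array(0, c(ensemble$n_trees, n, d, C))
  base <- matrix(0, ensemble$n_trees, C)
  for (k in trees) {
    tr <- ensemble$trees[[k]]
    for (i in seq_len(n)) {
      res <- tree_shap(tr, X[i, ], B, n_features = d)
      phi[k, i, , ] <- res$phi
      base[k, ] <- res$base
    }
  }
  list(phi = phi, base = base,
       feature_names = colnames(X), class_names = ensemble$classes)
}

#' Assemble the full SHAP tensor over hypothesis samples
#'
#' The tensor is indexed (hypothesis sample, tree slot, instance, feature,
#' class); storage is per unique tree, materialized on demand.
#'
#' @param samples list of `hypothesis_sample` objects.
#' @param per_tree output of [per_tree_shap()].
#' @return A `shap_tensor` object; `as.array()` materializes the 5-d array,
#'   `base_values()` fetches the (sample, slot, class) base array.
#' @export
shap_tensor <- function(samples, per_tree) {
  structure(list(samples = samples, per_tree = per_tree,
                 feature_names = per_tree$feature_names,
                 class_names = per_tree$class_names),
            class = "shap_tensor")
}

#' @export
as.array.shap_tensor <- function(x, ...) {
  S <- length(x$samples)
  n_draw <- length(x$samples[[1]]$tree_indices)
  dims <- dim(x$per_tree$phi)  # K, n, d, C
  out <- array(NA_real_, c(S, n_draw, dims[2], dims[3], dims[4]))
  for (s in seq_len(S))
    out[s, , , , ] <- x$per_tree$phi[x$samples[[s]]$tree_indices, , , ,
                                     drop = FALSE]
  out
}

#' @rdname shap_tensor
#' @param x a `shap_tensor`.
#' @export
base_values <- function(x) {
  S <- length(x$samples)
  n_draw <- length(x$samples[[1]]$tree_indices)
  C <- ncol(x$per_tree$base)
  out <- array(NA_real_, c(S, n_draw, C))
  for (s in seq_len(S))
    out[s, , ] <- x$per_tree$base[x$samples[[s]]$tree_indices, , drop = FALSE]
  out
}
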