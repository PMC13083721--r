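#' Build a single decision-tree view from a node table
#'
#' A `tree_view` is a minimal introspectable representation of a binary
#' decision tree: internal nodes carry a feature index and threshold, leaves
#' carry a per-class score vector. The prediction rule is root-to-leaf
#' traversal with the convention `x[feature] <= threshold` goes left.
#'
#' @param feature integer vector, 1-based feature index per node (`NA` at
#'   leaves).
#' @param threshold numeric vector, split threshold per node (`NA` at leaves).
#' @param left,right integer vectors, 1-based child node ids (`NA` at leaves).
#' @param values numeric matrix, one row per node; rows at leaf nodes are the
#'   per-class score vectors (internal-node rows are ignored).
#' @param classes character vector of class labels; `ncol(values)` must equal
#'   its length.
#' @return An object of class `tree_view`.
#' @examples
#' # a stump on feature 1: x1 <= 0 -> score 0, else score 10
#' tr <- tree_view(feature = c(1, NA, NA), threshold = c(0, NA, NA),
#'                 left = c(2, NA, NA), right = c(3, NA, NA),
#'                 values = rbind(0, 0, 10), classes = "pos")
#' predict(tr, data.frame(x1 = c(-1, 1)))
#' @export
tree_view <- function(feature, threshold, left, right, values, classes) {
  n <- length(feature)
  values <- as.matrix(values)
  stopifnot(length(threshold) == n, length(left) == n, length(right) == n,
            nrow(values) == n)
  if (length(classes) != ncol(values))
    stop("`classes` length must match ncol(values)")
  is_leaf <- is.na(feature)
  if (!any(is_leaf)) stop("tree has no leaves")
  bad <- which(!is_leaf & (is.na(left) | is.na(right) | is.na(threshold)))
  if (length(bad))
    stop("malformed node table: internal node ", bad[1],
         " lacks threshold or children")
  bad_child <- which(!is_leaf & (left < 1 | left > n | right < 1 | right > n))
  if (length(bad_child))
    stop("malformed node table: node ", bad_child[1],
         " references child outside table")
  if (any(!is.finite(values[is_leaf, , drop = FALSE])))
    stop("leaf value vectors must be finite")
  dimnames(values) <- NULL
  obj <- structure(list(
    feature = as.integer(feature), threshold = as.numeric(threshold),
    left = as.integer(left), right = as.integer(right),
    values = values, classes = as.character(classes),
    is_leaf = is_leaf), class = "tree_view")
  obj$leaves <- .tree_leaf_boxes(obj)
  obj
}

# Per-leaf path constraints: for each leaf, the distinct features used on its
# root path and the half-open interval (lo, hi] each must satisfy.
.tree_leaf_boxes <- function(tree) {
  out <- list()
  walk <- function(node, lo, hi) {
    if (tree$is_leaf[node]) {
      used <- which(is.finite(lo) | is.finite(hi))
      out[[length(out) + 1L]] <<- list(
        node = node, used = used,
        lo = lo[used], hi = hi[used],
        value = tree$values[node, ])
      return(invisible())
    }
    f <- tree$feature[node]; t <- tree$threshold[node]
    hi2 <- hi; hi2[f] <- min(hi[f], t, na.rm = TRUE)
    walk(tree$left[node], lo, hi2)
    lo2 <- lo; lo2[f] <- max(lo[f], t, na.rm = TRUE)
    walk(tree$right[node], lo2, hi)
  }
  d <- max(1L, suppressWarnings(max(tree$feature, na.rm = TRUE)))
  if (!is.finite(d)) d <- 1L
  walk(1L, rep(-Inf, d), rep(Inf, d))
  out
}

#' @export
predict.tree_view <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(object$classes),
                dimnames = list(NULL, object$classes))
  # vectorized recursive partition of row indices
  assign_rows <- function(node, rows) {
    if (!length(rows)) return(invisible())
    if (object$is_leaf[node]) {
      out[rows, ] <<- matrix(object$values[node, ], length(rows),
                             ncol(out), byrow = TRUE)
      return(invisible())
    }
    goes_left <- X[rows, object$feature[node]] <= object$threshold[node]
    assign_rows(object$left[node], rows[goes_left])
    assign_rows(object$right[node], rows[!goes_left])
  }
  assign_rows(1L, seq_len(n))
  out
}

#' Build an introspectable view of a bagged tree ensemble
#'
#' @param trees list of [tree_view] objects sharing the same class set.
#' @param classes character vector of class labels.
#' @param bootstrap_masks optional logical matrix (`n_train` rows x `K`
#'   trees); `TRUE` marks a row as in-bag for that tree. Out-of-bag rows of
#'   tree `k` are the `FALSE` entries of column `k`.
#' @return An object of class `ensemble_view` with fields `trees`, `n_trees`,
#'   `classes`, `bootstrap_masks`.
#' @seealso [as_ensemble_view()] to convert a fitted `ranger` forest,
#'   [read_tree_dump()] for the JSON interchange format.
#' @export
ensemble_view <- function(trees, classes, bootstrap_masks = NULL) {
  if (length(trees) < 2L) stop("an ensemble needs K >= 2 trees")
  for (tr in trees) {
    if (!inherits(tr, "tree_view")) stop("all trees must be tree_view objects")
    if (!identical(tr$classes, as.character(classes)))
      stop("all trees must predict over the same classes")
  }
  if (!is.null(bootstrap_masks)) {
    bootstrap_masks <- as.matrix(bootstrap_masks)
    if (ncol(bootstrap_masks) != length(trees))
      stop("bootstrap_masks must have one column per tree")
    storage.mode(bootstrap_masks) <- "logical"
  }
  structure(list(trees = trees, n_trees = length(trees),
                 classes = as.character(classes),
                 bootstrap_masks = bootstrap_masks),
            class = "ensemble_view")
}

#' @export
print.ensemble_view <- function(x, ...) {
  cat("Tree ensemble view: K =", x$n_trees, "trees,",
      length(x$classes), "classes (", paste(x$classes, collapse = ", "), ")\n")
  cat("bootstrap masks:", if (is.null(x$bootstrap_masks)) "absent"
      else paste(nrow(x$bootstrap_masks), "training rows"), "\n")
  invisible(x)
}

#' Ensemble prediction: per-class scores averaged over trees
#'
#' @param object an `ensemble_view`.
#' @param newdata data frame or matrix of features.
#' @param trees optional integer vector (with multiplicity) selecting a
#'   sub-ensemble; defaults to all trees once each.
#' @param ... unused.
#' @export
predict.ensemble_view <- function(object, newdata, trees = NULL, ...) {
  idx <- if (is.null(trees)) seq_len(object$n_trees) else as.integer(trees)
  acc <- 0
  for (k in idx) acc <- acc + predict(object$trees[[k]], newdata)
  acc / length(idx)
}

#' Convert a fitted ranger probability forest into an ensemble view
#'
#' Requires `probability = TRUE` (leaves hold class-probability vectors) and,
#' for out-of-bag weighting, `keep.inbag = TRUE`.
#'
#' @param x a `ranger` fit.
#' @param ... unused.
#' @return An `ensemble_view`.
#' @export
as_ensemble_view <- function(x, ...) UseMethod("as_ensemble_view")

#' @rdname as_ensemble_view
#' @export
as_ensemble_view.ranger <- function(x, ...) {
  if (x$treetype != "Probability estimation")
    stop("train ranger with probability = TRUE")
  classes <- colnames(x$predictions)
  if (is.null(classes)) classes <- as.character(x$forest$class.values)
  trees <- lapply(seq_len(x$num.trees), function(k) {
    ti <- ranger::treeInfo(x, k)
    vcols <- grep("^pred\\.", names(ti))
    if (!length(vcols)) vcols <- grep("^prediction", names(ti))
    vals <- as.matrix(ti[, vcols, drop = FALSE])
    vals[is.na(vals)] <- 0
    tree_view(feature = ti$splitvarID + 1L,
              threshold = ti$splitval,
              left = ti$leftChild + 1L, right = ti$rightChild + 1L,
              values = vals, classes = classes)
  })
  masks <- NULL
  if (!is.null(x$inbag.counts))
    masks <- do.call(cbind, lapply(x$inbag.counts, function(cc) cc > 0))
  ensemble_view(trees, classes, masks)
}

#' @rdname as_ensemble_view
#' @export
as_ensemble_view.ensemble_view <- function(x, ...) x

#' Read / write the JSON tree-dump interchange format
#'
#' Each tree is a node table with fields `node_id`, `feature`, `threshold`,
#' `left`, `right` (1-based ids, `null`/`NA` at leaves) and `leaf_values`
#' (per-class score vector). The top level holds `classes` and `trees`, and
#' optionally `bootstrap_masks` (row-major 0/1 matrix).
#'
#' @param path file path.
#' @return `read_tree_dump` returns an `ensemble_view`.
#' @export
read_tree_dump <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  classes <- vapply(js$classes, as.character, "")
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  trees <- lapply(js$trees, function(tb) {
    ord <- order(vapply(tb$node_id, as.integer, 1L))
    field <- function(nm) vapply(tb[[nm]], num_or_na, 1)[ord]
    vals <- do.call(rbind, lapply(tb$leaf_values[ord], function(v)
      if (is.null(v) || all(vapply(v, is.null, TRUE))) rep(0, length(classes))
      else vapply(v, as.numeric, 1)))
    tree_view(field("feature"), field("threshold"),
              field("left"), field("right"), vals, classes)
  })
  masks <- NULL
  if (!is.null(js$bootstrap_masks))
    masks <- do.call(rbind, lapply(js$bootstrap_masks, function(row)
      vapply(row, as.numeric, 1) > 0))
  ensemble_view(trees, classes, masks)
}

#' @rdname read_tree_dump
#' @param ensemble an `ensemble_view`.
#' @export
write_tree_dump <- function(ensemble, path) {
  trees <- lapply(ensemble$trees, function(tr) {
    n <- length(tr$feature)
    list(node_id = seq_len(n), feature = tr$feature,
         threshold = tr$threshold, left = tr$left, right = tr$right,
         leaf_values = lapply(seq_len(n), function(i)
           if (tr$is_leaf[i]) unname(tr$values[i, ]) else NA))
  })
  out <- list(classes = ensemble$classes, trees = trees)
  if (!is.null(ensemble$bootstrap_masks))
    out$bootstrap_masks <- unname(ensemble$bootstrap_masks * 1L)
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}
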