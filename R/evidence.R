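#' Partition the observed SHAP range into equal-width cells
#'
#' The frame of discernment for the evidence layer: M disjoint, contiguous
#' half-open intervals `[l_j, u_j)` (the last cell closed) covering the
#' observed range.
#'
#' @param shap_samples numeric vector of observed values (>= 2 distinct for a
#'   proper partition).
#' @param M number of cells (>= 2).
#' @return List of class `shap_partition` with `breaks` (length M + 1), `M`,
#'   and `degenerate` (TRUE single-cell partition when all values coincide).
#' @export
build_partition <- function(shap_samples, M) {
  if (M < 2) stop("M must be >= 2")
  lo <- min(shap_samples); hi <- max(shap_samples)
  if (lo == hi)
    return(structure(list(breaks = c(lo, hi), M = 1L, degenerate = TRUE),
                     class = "shap_partition"))
  structure(list(breaks = seq(lo, hi, length.out = M + 1), M = as.integer(M),
                 degenerate = FALSE),
            class = "shap_partition")
}

# Map values to cell indices; values outside the range clamp with a warning.
.partition_cells_of <- function(partition, v) {
  lo <- partition$breaks[1]
  hi <- partition$breaks[length(partition$breaks)]
  if (partition$degenerate) return(rep(1L, length(v)))
  if (any(v < lo | v > hi))
    warning("value(s) outside partition range clamped to nearest cell")
  width <- (hi - lo) / partition$M
  idx <- floor((v - lo) / width) + 1
  pmin(pmax(as.integer(idx), 1L), partition$M)
}

#' Basic probability assignment from per-source SHAP values
#'
#' Each evidence source (a hypothesis sub-ensemble) contributes mass
#' `1 / n_sources` to the focal element formed by the set of cells its
#' per-tree SHAP values hit. Sources whose values all fall in one cell give
#' singleton (Bayesian) evidence; dispersed sources give genuinely
#' set-valued evidence, opening a belief-plausibility gap.
#'
#' @param per_source_values list of numeric vectors, one per source.
#' @param partition a [build_partition()] result.
#' @return A `mass_function`: `focal` (list of sorted integer cell sets),
#'   `mass` (summing to 1), `M`.
#' @export
build_bpa <- function(per_source_values, partition) {
  if (!length(per_source_values)) stop("need at least one evidence source")
  if (!is.list(per_source_values)) per_source_values <- list(per_source_values)
  n <- length(per_source_values)
  all_v <- unlist(per_source_values)
  lo <- partition$breaks[1]; hi <- partition$breaks[length(partition$breaks)]
  if (!partition$degenerate && any(all_v < lo | all_v > hi))
    warning("value(s) outside partition range clamped to nearest cell")
  focal_keys <- vapply(per_source_values, function(v) {
    cells <- sort(unique(suppressWarnings(.partition_cells_of(partition, v))))
    paste(cells, collapse = ",")
  }, "")
  tab <- table(focal_keys)
  focal <- lapply(names(tab), function(k) as.integer(strsplit(k, ",")[[1]]))
  structure(list(focal = focal, mass = as.numeric(tab) / n,
                 M = partition$M),
            class = "mass_function")
}

#' Belief and plausibility of a cell set
#'
#' `belief(A)` sums the mass of focal elements contained in `A` (confirmed
#' support); `plausibility(A)` sums the mass of focal elements intersecting
#' `A` (possible support). Always `0 <= Bel(A) <= Pl(A) <= 1` and
#' `Bel(A) + Pl(complement of A) = 1`.
#'
#' @param m a `mass_function`.
#' @param A integer vector of cell indices.
#' @return Value in `[0, 1]`.
#' @export
belief <- function(m, A) {
  sum(m$mass[vapply(m$focal, function(f) all(f %in% A), TRUE)])
}

#' @rdname belief
#' @export
plausibility <- function(m, A) {
  sum(m$mass[vapply(m$focal, function(f) any(f %in% A), TRUE)])
}

#' Explanation conflict of a mass function
#'
#' The maximum ambiguity `Pl({j}) - Bel({j})` over single cells of the
#' partition. Zero for purely singleton (Bayesian) evidence; 1 when all mass
#' sits on multi-cell focal elements covering a cell without confirming it.
#' High conflict flags features whose attribution evidence is contradictory
#' across sub-ensembles.
#'
#' @param m a `mass_function`.
#' @param partition the partition `m` was built on (only `M` is used).
#' @return Value in `[0, 1]`.
#' @export
conflict <- function(m, partition = NULL) {
  M <- if (is.null(partition)) m$M else partition$M
  max(vapply(seq_len(M), function(j)
    plausibility(m, j) - belief(m, j), 1))
}

#' Empirical uncertainty distribution of a SHAP sample
#'
#' The monotone degree-of-belief function that the attribution is at most a
#' threshold: 0 below the observed minimum, 1 at and above the maximum,
#' nondecreasing in between, crossing 0.5 at the sample median. Implemented
#' as the empirical CDF of the observed values.
#'
#' @param shap_samples numeric vector (>= 2 values).
#' @return List of class `uncertainty_cdf` with `values` (sorted support)
#'   and `fun` (a step function `numeric -> [0, 1]`).
#' @export
uncertainty_cdf <- function(shap_samples) {
  if (length(shap_samples) < 2) stop("need >= 2 values")
  structure(list(values = sort(as.numeric(shap_samples)),
                 fun = stats::ecdf(shap_samples)),
            class = "uncertainty_cdf")
}

#' @export
print.uncertainty_cdf <- function(x, ...) {
  cat("uncertainty distribution on [", min(x$values), ",", max(x$values),
      "], n =", length(x$values), "\n")
  invisible(x)
}

#' Entropy of an uncertainty distribution
#'
#' Differential entropy of the density underlying the uncertainty
#' distribution, estimated from its support sample with the same
#' kernel-density estimator as [entropy_estimate()] (shared implementation).
#'
#' @param g an [uncertainty_cdf()] result.
#' @return Entropy in nats; `-Inf` sentinel for zero spread.
#' @export
gamma_entropy <- function(g) {
  if (max(g$values) == min(g$values))
    return(structure(-Inf, degenerate = TRUE))
  entropy_estimate(g$values)
}

#' Rank features by expected uncertainty-entropy reduction
#'
#' The marginal entropy reduction from acquiring data on a feature scales
#' with its attribution variance, so features sort descending by SHAP
#' variance, with entropy as tie-break. The head of the list is where new
#' data buys the most certainty.
#'
#' @param variance named numeric vector of per-feature SHAP variances.
#' @param entropy numeric vector of per-feature uncertainty entropies
#'   (same length/order).
#' @return Integer permutation (with names if `variance` is named) giving
#'   the acquisition order.
#' @export
acquisition_ranking <- function(variance, entropy = rep(0, length(variance))) {
  if (!length(variance)) stop("need at least one feature")
  ord <- order(-variance, -entropy)
  if (!is.null(names(variance))) names(ord) <- names(variance)[ord]
  ord
}
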