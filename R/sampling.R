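#' Configuration for Dirichlet hypothesis sampling
#'
#' @param alpha positive concentration parameter. Small `alpha` concentrates
#'   draws on few high-weight trees (exploitation); large `alpha` makes the
#'   Dirichlet draw track the base measure `w` (exploration).
#' @param beta nonnegative softmax temperature for the base measure.
#' @param n_samples number of hypothesis samples S (>= 2).
#' @param n_draw trees per sub-ensemble, drawn with replacement; `NULL` means
#'   "same size as the parent ensemble" (Bayesian-bootstrap reading).
#' @param seed integer root seed; every sample gets its own substream derived
#'   from it, so increasing `n_samples` never perturbs earlier samples.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(alpha = 0.5, beta = 5, n_samples = 20,
                            n_draw = NULL, seed = 42) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (!is.null(n_draw) && n_draw < 1) stop("n_draw must be >= 1")
  structure(list(alpha = alpha, beta = beta,
                 n_samples = as.integer(n_samples),
                 n_draw = if (is.null(n_draw)) NULL else as.integer(n_draw),
                 seed = as.integer(seed)),
            class = "sampling_config")
}

.substream_seed <- function(seed, s) {
  # decorrelate substreams from (root seed, sample index); keep < 2^31
  (as.numeric(seed) %% 2147483629) * 69069 %% 2147483629 * 1 + s * 40503
}

#' Draw hypothesis sub-ensembles from the Dirichlet posterior over trees
#'
#' For each of S samples, a simplex vector `pi ~ Dirichlet(alpha * w)` is
#' drawn (parameter entries floored at 1e-8), then `n_draw` tree indices are
#' drawn i.i.d. from `Categorical(pi)` with replacement. Each sample is a
#' plausible sub-ensemble — one hypothesis about what the forest believes.
#'
#' @param w simplex weight vector over the K trees (the base measure).
#' @param config a [sampling_config].
#' @return List of S `hypothesis_sample` objects, each with fields `pi`,
#'   `tree_indices`, `sample_id`, `seed_state`.
#' @export
dirichlet_sample <- function(w, config) {
  K <- length(w)
  if (K < 2) stop("need K >= 2 trees")
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) stop("w must lie on the simplex")
  av <- config$alpha * w
  if (all(av < 1e-8)) stop("degenerate concentration: all alpha * w below floor")
  av <- pmax(av, 1e-8)
  n_draw <- if (is.null(config$n_draw)) K else config$n_draw
  lapply(seq_len(config$n_samples), function(s) {
    sub_seed <- .substream_seed(config$seed, s) %% 2147483629
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(sub_seed)
    g <- stats::rgamma(K, shape = av, rate = 1)
    if (sum(g) <= 0) {  # gamma underflow at tiny shapes: degenerate one-hot
      pi <- rep(0, K)
      pi[sample.int(K, 1L, prob = av / sum(av))] <- 1
    } else pi <- g / sum(g)
    idx <- sample.int(K, n_draw, replace = TRUE, prob = pi)
    structure(list(pi = pi, tree_indices = idx, sample_id = s,
                   seed_state = sub_seed),
              class = "hypothesis_sample")
  })
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Effective number of distinct trees in each hypothesis sample
#'
#' The exponential of the Shannon entropy of the tree-index frequencies: 1
#' when a sub-ensemble repeats a single tree, K when all K trees appear
#' equally often. A diagnostic for the exploration-exploitation balance that
#' the concentration parameter controls.
#'
#' @param samples list of `hypothesis_sample` objects.
#' @return Numeric vector, one value in `[1, K]` per sample.
#' @export
effective_diversity <- function(samples) {
  if (!length(samples)) stop("no samples")
  vapply(samples, function(s) {
    p <- tabulate(s$tree_indices) / length(s$tree_indices)
    p <- p[p > 0]
    exp(-sum(p * log(p)))
  }, 1)
}
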