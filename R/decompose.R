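#' Decompose SHAP variability into aleatoric, epistemic, entanglement parts
#'
#' Within each hypothesis sample the per-tree SHAP values are the
#' within-sample replicates; across samples the sub-ensemble means are the
#' between-sample units. Per feature:
#' \describe{
#'   \item{aleatoric `A`}{mean over samples of the within-sample variance —
#'     irreducible attribution spread among the trees a hypothesis retains.}
#'   \item{epistemic `E`}{variance over samples of the within-sample mean —
#'     disagreement between plausible sub-models.}
#'   \item{entanglement `C`}{covariance between within-sample mean and
#'     within-sample variance — the model/data coupling term; any sign.}
#' }
#' All moments use the population convention (divide by the count), so the
#' identities checked in the tests are exact. The reported
#' `total = A + E - C` follows the corrected decomposition in which a
#' positive entanglement (aligned uncertainty sources) reduces total
#' variance. When model and data are independent the entanglement vanishes.
#'
#' @param shap_by_sample per-sample replicate values: a list of S numeric
#'   matrices (replicates x features) with a common number of columns, or a
#'   3-d array (sample, replicate, feature). A list of plain vectors is
#'   treated as single-feature matrices.
#' @return An `uncertainty_decomposition`: per-feature vectors `aleatoric`,
#'   `epistemic`, `entanglement`, `total`, plus the per-sample moments
#'   `mu_s` and `sigma2_s` (S x features matrices).
#' @examples
#' # two samples with per-tree values {1,3} and {2,6} for one feature
#' d <- decompose_variance(list(matrix(c(1, 3)), matrix(c(2, 6))))
#' d$aleatoric    # 2.5
#' d$epistemic    # 1.0
#' d$entanglement # 1.5
#' @export
decompose_variance <- function(shap_by_sample) {
  if (is.array(shap_by_sample) && length(dim(shap_by_sample)) == 3) {
    shap_by_sample <- lapply(seq_len(dim(shap_by_sample)[1]), function(s) {
      m <- shap_by_sample[s, , ]
      dim(m) <- dim(shap_by_sample)[2:3]
      m
    })
  }
  shap_by_sample <- lapply(shap_by_sample, function(m)
    if (is.matrix(m)) m else matrix(m, ncol = 1))
  S <- length(shap_by_sample)
  if (S < 2) stop("epistemic variance undefined: need S >= 2 samples")
  d <- ncol(shap_by_sample[[1]])
  mu_s <- t(vapply(shap_by_sample, colMeans, numeric(d)))
  sigma2_s <- t(vapply(shap_by_sample, function(m) {
    .colvar_pop(m)
  }, numeric(d)))
  dim(mu_s) <- c(S, d); dim(sigma2_s) <- c(S, d)
  A <- colMeans(sigma2_s)
  E <- .colvar_pop(mu_s)
  C <- vapply(seq_len(d), function(j)
    .cov_pop(mu_s[, j], sigma2_s[, j]), 1)
  structure(list(aleatoric = A, epistemic = E, entanglement = C,
                 total = A + E - C, mu_s = mu_s, sigma2_s = sigma2_s),
            class = "uncertainty_decomposition")
}

.colvar_pop <- function(m) colMeans(m^2) - colMeans(m)^2
.cov_pop <- function(x, y) mean(x * y) - mean(x) * mean(y)

#' @export
print.uncertainty_decomposition <- function(x, ...) {
  df <- data.frame(feature = seq_along(x$aleatoric),
                   aleatoric = x$aleatoric, epistemic = x$epistemic,
                   entanglement = x$entanglement, total = x$total)
  cat("SHAP uncertainty decomposition (", nrow(x$mu_s), "hypothesis samples )\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Importance-versus-uncertainty entanglement correlation
#'
#' Pearson correlation between per-feature importance (mean absolute SHAP)
#' and per-feature instability (standard deviation of SHAP across hypothesis
#' samples). A high positive correlation means the features the model leans
#' on hardest are also the ones it is least sure how to credit.
#'
#' @param importance numeric vector of per-feature mean |SHAP|.
#' @param spread numeric vector of per-feature SHAP standard deviations.
#' @return List of class `entanglement_correlation` with `rho`, the two
#'   vectors, and `degenerate` (TRUE with `rho = NA` when either vector has
#'   zero variance).
#' @export
entanglement_correlation <- function(importance, spread) {
  stopifnot(length(importance) == length(spread))
  if (length(importance) < 3)
    stop("need >= 3 features for a meaningful correlation")
  if (stats::sd(importance) == 0 || stats::sd(spread) == 0)
    return(structure(list(rho = NA_real_, importance = importance,
                          spread = spread, degenerate = TRUE),
                     class = "entanglement_correlation"))
  structure(list(rho = stats::cor(importance, spread),
                 importance = importance, spread = spread,
                 degenerate = FALSE),
            class = "entanglement_correlation")
}

#' @export
print.entanglement_correlation <- function(x, ...) {
  if (x$degenerate) cat("entanglement correlation: undefined (zero variance)\n")
  else cat(sprintf("entanglement correlation: rho = %.3f over %d features\n",
                   x$rho, length(x$importance)))
  invisible(x)
}
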