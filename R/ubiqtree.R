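#' Fit an uncertainty-decomposed SHAP explanation of a tree ensemble
#'
#' The main entry point. Trains (or ingests) a bagged probability forest,
#' weights its trees by out-of-bag accuracy through a softmax base measure,
#' draws Dirichlet hypothesis sub-ensembles, computes exact interventional
#' per-tree SHAP values over an explanation set, and summarizes the
#' resulting attribution distributions per feature and class: mean, spread,
#' 95% credible interval, differential entropy, sign stability, the
#' aleatoric/epistemic/entanglement variance decomposition, and the
#' Dempster-Shafer belief layer.
#'
#' @param formula model formula, e.g. `y ~ .`.
#' @param data data frame holding the target and features. Non-numeric
#'   feature columns are label-encoded (alphabetical level order) and the
#'   encoding is kept on the fit.
#' @param ensemble optional pre-trained ensemble ([ensemble_view], `ranger`
#'   fit, or anything [as_ensemble_view()] accepts). When omitted a ranger
#'   probability forest is trained on a stratified split of `data`.
#' @param alpha Dirichlet concentration (> 0). Small values concentrate
#'   hypothesis draws on few high-weight trees; large values track the
#'   softmax base measure.
#' @param beta softmax temperature (>= 0) for the out-of-bag weights.
#' @param n_samples number of hypothesis samples S.
#' @param n_draw trees per sub-ensemble (default: ensemble size, with
#'   replacement).
#' @param n_trees,max_depth forest size/depth when training internally.
#' @param n_background maximum background rows for the interventional SHAP
#'   value function (subsampled reproducibly from the training split).
#' @param n_explain maximum explanation instances (stratified subsample of
#'   the evaluation split).
#' @param partition_cells cells M for the evidence-layer partition.
#' @param train_fraction stratified train share when training internally.
#' @param seed root seed for every random stage.
#' @param holdout optional `list(X =, y =)` used to score trees when the
#'   ensemble carries no bootstrap masks.
#' @param keep_tensor keep the per-tree SHAP array on the fit (memory heavy;
#'   needed only for tensor-level introspection).
#' @return An object of class `ubiqtree`; see [summary.ubiqtree()],
#'   [plot.ubiqtree()], [coef.ubiqtree()].
#' @examples
#' \donttest{
#' ds <- make_dataset(scenario_config(n_rows = 300, seed = 7))
#' fit <- ubiqtree(y ~ ., cbind(ds$X, y = ds$y), n_trees = 20,
#'                 n_samples = 10, n_explain = 40, seed = 7)
#' summary(fit)
#' }
#' @export
ubiqtree <- function(formula, data, ensemble = NULL,
                     alpha = 0.5, beta = 5, n_samples = 20, n_draw = NULL,
                     n_trees = 50, max_depth = NULL,
                     n_background = 128, n_explain = 200,
                     partition_cells = 10, train_fraction = 0.7,
                     seed = 42, holdout = NULL, keep_tensor = FALSE) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- factor(stats::model.response(mf))
  if (nlevels(y) < 2) stop("target must have >= 2 classes")
  Xdf <- mf[, -1, drop = FALSE]
  enc <- .label_encode(Xdf)
  X <- enc$X
  feature_names <- colnames(X)

  if (is.null(ensemble)) {
    idx_tr <- .stratified_indices(y, train_fraction, seed = seed + 101L)
    X_tr <- X[idx_tr, , drop = FALSE]; y_tr <- droplevels(y[idx_tr])
    X_ev <- X[-idx_tr, , drop = FALSE]; y_ev <- y[-idx_tr]
    rf <- ranger::ranger(x = as.data.frame(X_tr), y = y_tr,
                         num.trees = n_trees, probability = TRUE,
                         keep.inbag = TRUE, seed = seed,
                         max.depth = if (is.null(max_depth)) 0 else max_depth,
                         num.threads = 1)
    ensemble <- as_ensemble_view(rf)
    pr <- predict(ensemble, as.matrix(X_ev))
    holdout_accuracy <- mean(ensemble$classes[
      max.col(pr, ties.method = "first")] == as.character(y_ev))
  } else {
    ensemble <- as_ensemble_view(ensemble)
    X_tr <- X; y_tr <- y; X_ev <- X; y_ev <- y
    holdout_accuracy <- NA_real_
  }
  if (ensemble$n_trees < 2) stop("model without trees (K < 2)")

  a <- compute_per_tree_oob_accuracy(ensemble, X_tr, y_tr, holdout = holdout)
  w <- softmax_weights(a, beta)
  scfg <- sampling_config(alpha = alpha, beta = beta, n_samples = n_samples,
                          n_draw = n_draw, seed = seed)
  samples <- dirichlet_sample(w, scfg)

  bg_idx <- .subsample_indices(nrow(X_tr), n_background, seed = seed + 202L)
  B <- X_tr[bg_idx, , drop = FALSE]
  if (nrow(X_ev) == 0L) { X_ev <- X_tr; y_ev <- y_tr }
  ex_idx <- .stratified_subsample(y_ev, n_explain, seed = seed + 303L)
  X_ex <- X_ev[ex_idx, , drop = FALSE]

  per_tree <- per_tree_shap(ensemble, X_ex, B)
  res <- .summarize_samples(samples, per_tree, partition_cells)

  structure(c(res, list(
    call = cl, classes = ensemble$classes, feature_names = feature_names,
    oob_accuracy = a, holdout_accuracy = holdout_accuracy,
    weights = w, samples = samples, ensemble = ensemble,
    encoding = enc$maps,
    n_explain = nrow(X_ex), n_background = nrow(B),
    config = list(alpha = alpha, beta = beta, n_samples = n_samples,
                  n_draw = scfg$n_draw, n_trees = ensemble$n_trees,
                  max_depth = max_depth, n_background = nrow(B),
                  n_explain = nrow(X_ex), partition_cells = partition_cells,
                  train_fraction = train_fraction, seed = seed),
    per_tree = if (keep_tensor) per_tree else NULL)),
    class = "ubiqtree")
}

# integer label-encoding for non-numeric feature columns
.label_encode <- function(Xdf) {
  maps <- list()
  for (nm in names(Xdf)) {
    col <- Xdf[[nm]]
    if (!is.numeric(col)) {
      f <- factor(col)
      maps[[nm]] <- levels(f)
      Xdf[[nm]] <- as.integer(f) - 1L
    }
  }
  list(X = as.matrix(Xdf), maps = maps)
}

.stratified_indices <- function(y, fraction, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  unlist(lapply(split(seq_along(y), y), function(ix)
    sort(sample(ix, max(1L, round(length(ix) * fraction))))),
    use.names = FALSE)
}

.subsample_indices <- function(n, k, seed) {
  if (n <= k) return(seq_len(n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sort(sample.int(n, k))
}

.stratified_subsample <- function(y, k, seed) {
  n <- length(y)
  if (n <= k) return(seq_len(n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  per <- ceiling(k * table(y) / n)
  ix <- unlist(lapply(split(seq_len(n), y), function(g)
    sample(g, min(length(g), per[[as.character(y[g[1]])]]))),
    use.names = FALSE)
  sort(ix[seq_len(min(k, length(ix)))])
}

# Core per-class summary over hypothesis samples: decomposition, report,
# evidence, entanglement. Instance-level components are averaged over the
# explanation set for the class-level report.
.summarize_samples <- function(samples, per_tree, partition_cells) {
  S <- length(samples)
  K <- dim(per_tree$phi)[1]; n <- dim(per_tree$phi)[2]
  d <- dim(per_tree$phi)[3]; C <- dim(per_tree$phi)[4]
  fn <- per_tree$feature_names
  if (is.null(fn)) fn <- paste0("x", seq_len(d))
  cn <- per_tree$class_names

  # per-sample moments over tree slots, per (sample, instance, feature, class)
  mu <- array(0, c(S, n, d, C)); s2 <- array(0, c(S, n, d, C))
  for (s in seq_len(S)) {
    idx <- samples[[s]]$tree_indices
    sl <- per_tree$phi[idx, , , , drop = FALSE]
    m1 <- colMeans(sl, dims = 1)
    mu[s, , , ] <- m1
    s2[s, , , ] <- colMeans(sl^2, dims = 1) - m1^2
  }

  report <- decomp <- NULL
  evidence <- list(); entangle <- list()
  mu_bar <- array(0, c(S, d, C), dimnames = list(NULL, fn, cn))
  for (ci in seq_len(C)) {
    # instance-averaged per-sample mean SHAP: S x d
    mb <- colMeans(aperm(mu[, , , ci, drop = FALSE], c(2, 1, 3, 4)), dims = 1)
    dim(mb) <- c(S, d)
    mu_bar[, , ci] <- mb
    # decomposition per instance, averaged over instances
    A <- E <- Cv <- matrix(0, n, d)
    for (ni in seq_len(n)) {
      mu_i <- mu[, ni, , ci]; s2_i <- s2[, ni, , ci]
      dim(mu_i) <- c(S, d); dim(s2_i) <- c(S, d)
      A[ni, ] <- colMeans(s2_i)
      E[ni, ] <- .colvar_pop(mu_i)
      Cv[ni, ] <- colMeans(mu_i * s2_i) - colMeans(mu_i) * colMeans(s2_i)
    }
    Af <- colMeans(A); Ef <- colMeans(E); Cf <- colMeans(Cv)
    decomp <- rbind(decomp, data.frame(
      class = cn[ci], feature = fn, aleatoric = Af, epistemic = Ef,
      entanglement = Cf, total = Af + Ef - Cf))
    # aggregation on the per-sample (instance-averaged) mean SHAP
    rows <- lapply(seq_len(d), function(j) aggregate_uncertainty(mb[, j]))
    report <- rbind(report, data.frame(
      class = cn[ci], feature = fn,
      mean_shap = vapply(rows, `[[`, 1, "mean"),
      std = vapply(rows, `[[`, 1, "std"),
      ci_low = vapply(rows, `[[`, 1, "ci_low"),
      ci_high = vapply(rows, `[[`, 1, "ci_high"),
      entropy_nats = vapply(rows, `[[`, 1, "entropy"),
      sign_stability = vapply(rows, `[[`, 1, "sign_stability"),
      stability_category = vapply(rows, `[[`, "", "stability_category"),
      action = vapply(rows, `[[`, "", "action")))
    # evidence layer: sources are sub-ensembles; per-source values are the
    # instance-averaged per-tree SHAP values the sub-ensemble contains
    tree_val <- colMeans(aperm(per_tree$phi[, , , ci, drop = FALSE],
                               c(2, 1, 3, 4)), dims = 1)  # K x d
    dim(tree_val) <- c(K, d)
    ev_class <- lapply(seq_len(d), function(j) {
      src <- lapply(samples, function(sm) tree_val[sm$tree_indices, j])
      pooled <- unlist(src)
      part <- build_partition(pooled, partition_cells)
      m <- build_bpa(src, part)
      Mj <- part$M
      list(feature = fn[j], cell_edges = part$breaks,
           degenerate = part$degenerate,
           bel = vapply(seq_len(Mj), function(c2) belief(m, c2), 1),
           pl = vapply(seq_len(Mj), function(c2) plausibility(m, c2), 1),
           conflict = conflict(m, part),
           gamma_entropy = if (S >= 10) gamma_entropy(uncertainty_cdf(mb[, j]))
                           else NA_real_)
    })
    names(ev_class) <- fn
    var_mb <- .colvar_pop(mb)
    gam <- vapply(ev_class, function(e)
      ifelse(is.finite(e$gamma_entropy), e$gamma_entropy, -Inf), 1)
    rank_ord <- acquisition_ranking(stats::setNames(var_mb, fn), gam)
    for (j in seq_len(d))
      ev_class[[j]]$acquisition_rank <- which(rank_ord == j)
    evidence[[cn[ci]]] <- ev_class
    # entanglement correlation: importance vs instability across features
    importance <- colMeans(abs(mb))
    spread <- sqrt(.colvar_pop(mb))
    entangle[[cn[ci]]] <- entanglement_correlation(importance, spread)
  }
  rownames(report) <- rownames(decomp) <- NULL
  list(report = report, decomposition = decomp, evidence = evidence,
       entanglement = entangle, mu_s = mu_bar)
}

#' @export
print.ubiqtree <- function(x, ...) {
  cat("ubiqtree explanation fit\n")
  cat("  trees K =", x$config$n_trees,
      "| hypothesis samples S =", x$config$n_samples,
      "| alpha =", x$config$alpha, "| beta =", x$config$beta, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", length(x$feature_names),
      "| explained instances:", x$n_explain,
      "| background rows:", x$n_background, "\n")
  cat("  mean per-tree OOB accuracy:",
      sprintf("%.3f", mean(x$oob_accuracy)), "\n")
  invisible(x)
}

#' Summarize an ubiqtree fit
#'
#' @param object an `ubiqtree` fit.
#' @param top_n features to display per class, ranked by importance.
#' @param ... unused.
#' @export
summary.ubiqtree <- function(object, top_n = 5, ...) {
  rep <- merge(object$report, object$decomposition,
               by = c("class", "feature"), sort = FALSE)
  imp <- vapply(seq_len(nrow(rep)), function(i)
    mean(abs(object$mu_s[, rep$feature[i], rep$class[i]])), 1)
  rep$importance <- imp
  rep <- rep[order(rep$class, -rep$importance), ]
  out <- do.call(rbind, lapply(split(rep, rep$class), utils::head, top_n))
  rownames(out) <- NULL
  structure(list(table = out,
                 rho = vapply(object$entanglement, `[[`, 1, "rho"),
                 config = object$config),
            class = "summary.ubiqtree")
}

#' @export
print.summary.ubiqtree <- function(x, ...) {
  cat("Top features per class (importance = mean |SHAP| across hypothesis samples)\n\n")
  df <- x$table
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  cat("\nImportance-vs-uncertainty entanglement correlation (Pearson rho):\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Mean SHAP attribution matrix
#'
#' @param object an `ubiqtree` fit.
#' @param ... unused.
#' @return Features x classes matrix of mean SHAP values (averaged over
#'   hypothesis samples and explanation instances).
#' @export
coef.ubiqtree <- function(object, ...) {
  matrix(object$report$mean_shap, nrow = length(object$feature_names),
         dimnames = list(object$feature_names, object$classes))
}

#' Predict class probabilities with the explained ensemble
#'
#' @param object an `ubiqtree` fit.
#' @param newdata data frame of features (same columns as the fit).
#' @param ... unused.
#' @return Matrix of per-class probabilities (full-ensemble average).
#' @export
predict.ubiqtree <- function(object, newdata, ...) {
  Xdf <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  for (nm in names(object$encoding))
    Xdf[[nm]] <- as.integer(factor(Xdf[[nm]],
                                   levels = object$encoding[[nm]])) - 1L
  predict(object$ensemble, as.matrix(Xdf))
}
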