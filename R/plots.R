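#' Plot an ubiqtree fit
#'
#' Three views per class, all in base graphics:
#' \describe{
#'   \item{summary}{top features by mean |SHAP| with the per-sample value
#'     cloud, a mean ± 2 sigma band, and a zero reference line.}
#'   \item{distribution}{kernel-density grid of the per-sample SHAP
#'     distributions for the top features, with mean line and 95% credible
#'     shading; degenerate (zero-spread) features get a point marker.}
#'   \item{entanglement}{importance versus instability scatter annotated
#'     with the Pearson correlation.}
#' }
#'
#' @param x an `ubiqtree` fit.
#' @param type one of `"summary"`, `"distribution"`, `"entanglement"`.
#' @param class class label to plot (default: first).
#' @param top_n number of features shown (15 for summary, 4 for the
#'   distribution grid by default).
#' @param ... unused.
#' @export
plot.ubiqtree <- function(x, type = c("summary", "distribution",
                                      "entanglement"),
                          class = NULL, top_n = NULL, ...) {
  type <- match.arg(type)
  cls <- if (is.null(class)) x$classes[1] else match.arg(class, x$classes)
  switch(type,
         summary = .plot_summary(x, cls,
                                 if (is.null(top_n)) 15 else top_n),
         distribution = .plot_distribution(x, cls,
                                           if (is.null(top_n)) 4 else top_n),
         entanglement = .plot_entanglement(x, cls))
  invisible(x)
}

.top_features <- function(x, cls, top_n) {
  imp <- colMeans(abs(x$mu_s[, , cls, drop = FALSE])[, , 1, drop = FALSE])
  dim(imp) <- NULL
  names(imp) <- x$feature_names
  names(sort(imp, decreasing = TRUE))[seq_len(min(top_n, length(imp)))]
}

.plot_summary <- function(x, cls, top_n) {
  feats <- rev(.top_features(x, cls, top_n))
  mu <- matrix(x$mu_s[, feats, cls], ncol = length(feats),
               dimnames = list(NULL, feats))
  m <- colMeans(mu)
  s <- sqrt(.colvar_pop(mu))
  xlim <- range(c(mu, m - 2 * s, m + 2 * s, 0))
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, length(feats) + 0.5),
                 yaxt = "n", xlab = "SHAP value (per-sample mean)",
                 ylab = "", main = paste0("Attribution summary, class ", cls,
                                          " (band = mean ± 2σ)"))
  graphics::axis(2, at = seq_along(feats), labels = feats, las = 1,
                 cex.axis = 0.8)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  for (j in seq_along(feats)) {
    graphics::segments(m[j] - 2 * s[j], j, m[j] + 2 * s[j], j,
                       col = "steelblue", lwd = 4)
    graphics::points(mu[, j], jitter(rep(j, nrow(mu)), amount = 0.12),
                     pch = 16, cex = 0.5, col = grDevices::adjustcolor("black", 0.4))
    graphics::points(m[j], j, pch = 18, cex = 1.4, col = "firebrick")
  }
}

.plot_distribution <- function(x, cls, top_n) {
  feats <- .top_features(x, cls, top_n)
  nf <- length(feats)
  nr <- ceiling(nf / 2)
  op <- graphics::par(mfrow = c(nr, min(2, nf)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (f in feats) {
    v <- x$mu_s[, f, cls]
    if (max(v) == min(v)) {
      graphics::plot(v[1], 0, pch = 17, col = "firebrick",
                     xlab = "SHAP value", ylab = "density",
                     main = paste0(f, " (degenerate)"))
      next
    }
    de <- stats::density(v)
    ci <- stats::quantile(v, c(0.025, 0.975), type = 7)
    graphics::plot(de, main = paste0(f, " | ", cls),
                   xlab = "SHAP value (per-sample mean)")
    sel <- de$x >= ci[1] & de$x <= ci[2]
    graphics::polygon(c(de$x[sel], rev(de$x[sel])),
                      c(de$y[sel], rep(0, sum(sel))),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::abline(v = mean(v), col = "firebrick", lty = 2)
  }
}

.plot_entanglement <- function(x, cls) {
  ec <- x$entanglement[[cls]]
  graphics::plot(ec$importance, ec$spread, pch = 16, col = "steelblue",
                 xlab = "importance (mean |SHAP|)",
                 ylab = "instability (sd of SHAP across samples)",
                 main = paste0("Importance vs uncertainty, class ", cls))
  graphics::text(ec$importance, ec$spread, labels = x$feature_names,
                 pos = 3, cex = 0.7)
  if (!ec$degenerate) {
    graphics::abline(stats::lm(ec$spread ~ ec$importance), col = "grey50",
                     lty = 2)
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("Pearson ρ = %.2f", ec$rho))
  }
}

#' Write the figure bundle for a fit
#'
#' Three figure families per class (summary, distribution grid,
#' entanglement scatter), written as PNG files into `out_dir`.
#'
#' @param fit an `ubiqtree` fit.
#' @param out_dir output directory (created if missing).
#' @param top_n features in the distribution grid.
#' @return Character vector of file paths, invisibly.
#' @export
render_reports <- function(fit, out_dir, top_n = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cls in fit$classes) {
    for (fam in c("summary", "distribution", "entanglement")) {
      fp <- file.path(out_dir, paste0(fam, "_", cls, ".png"))
      grDevices::png(fp, width = 900, height = 700)
      tryCatch(plot(fit, type = fam, class = cls, top_n =
                      if (fam == "distribution") top_n else NULL),
               finally = grDevices::dev.off())
      files <- c(files, fp)
    }
  }
  invisible(files)
}
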