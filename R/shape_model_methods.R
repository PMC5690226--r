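#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> fitted to %d DVFs on a %s grid\n",
              x$n_train, paste(x$grid$shape, collapse = " x ")))
  cat(sprintf("  nonzero modes: %d; retained T_hat = %d at alpha = %g%%\n",
              length(x$eigenvalues), x$T_hat, x$alpha))
  cat(sprintf("  total variance: %.4g mm^2; variation-space reduction: %.1f%%\n",
              x$total_variance, space_reduction(x$n_train, x$T_hat)))
  if (length(x$eigenvalues))
    cat("  leading eigenvalues:",
        paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted deformation shape model
#'
#' Reports the eigenvalue spectrum, per-mode and cumulative variance
#' coverage, the retained mode count and the variation-space reduction.
#'
#' @param object a `shape_model`.
#' @param ... unused.
#' @return a `summary.shape_model`: list with a per-mode `coverage` data
#'   frame and scalar fit descriptors.
#' @export
summary.shape_model <- function(object, ...) {
  lam <- object$eigenvalues
  cov <- if (length(lam)) {
    data.frame(mode = seq_along(lam), eigenvalue = lam,
               pct_variance = 100 * lam / sum(lam),
               cum_pct = 100 * cumsum(lam) / sum(lam))
  } else {
    data.frame(mode = integer(0), eigenvalue = numeric(0),
               pct_variance = numeric(0), cum_pct = numeric(0))
  }
  structure(list(coverage = cov, n_train = object$n_train,
                 T_hat = object$T_hat, alpha = object$alpha,
                 total_variance = object$total_variance,
                 space_reduction = space_reduction(object$n_train,
                                                   object$T_hat),
                 mean_magnitude_mm =
                   mean(sqrt(rowSums(matrix(object$mean,
                                            ncol = 3)^2)))),
            class = "summary.shape_model")
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat(sprintf("Active shape model of deformation (N = %d training DVFs)\n",
              x$n_train))
  cat(sprintf("  mean |deformation|: %.3f mm\n", x$mean_magnitude_mm))
  cat(sprintf("  T_hat = %d of %d nonzero modes at alpha = %g%% ",
              x$T_hat, nrow(x$coverage), x$alpha))
  cat(sprintf("(space reduction %.1f%%)\n", x$space_reduction))
  if (nrow(x$coverage)) {
    show <- head(x$coverage, 10)
    show$eigenvalue <- signif(show$eigenvalue, 4)
    show$pct_variance <- round(show$pct_variance, 2)
    show$cum_pct <- round(show$cum_pct, 2)
    print(show, row.names = FALSE)
    if (nrow(x$coverage) > 10)
      cat("  ... (", nrow(x$coverage) - 10, " more modes)\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.shape_model <- function(object, ...) {
  setNames(object$eigenvalues,
           paste0("lambda_", seq_along(object$eigenvalues)))
}

#' Reconstruct a deformation from mode weights
#'
#' Deterministic counterpart of [sample_deformation()]: evaluates
#' \eqn{d = \bar d + \sum_j b_j \phi_j} for given weights `b` (padded with
#' zeros beyond `length(b)`).
#'
#' @param object a `shape_model`.
#' @param b numeric weights for the leading modes (default: none, returns
#'   the mean deformation).
#' @param ... unused.
#' @return a [vector_field].
#' @export
predict.shape_model <- function(object, b = numeric(0), ...) {
  stopifnot(length(b) <= length(object$eigenvalues))
  v <- object$mean
  if (length(b))
    v <- v + as.vector(object$modes[, seq_along(b), drop = FALSE] %*% b)
  devectorize_field(v, object$grid)
}

#' Simulate random deformations from a shape model
#'
#' Draws `nsim` Mahalanobis-bounded random deformations (see
#' [sample_deformation()]).
#'
#' @param object a `shape_model`.
#' @param nsim number of deformations.
#' @param seed integer seed (required, for reproducibility).
#' @param D_max maximum Mahalanobis distance.
#' @param ... unused.
#' @return list of `nsim` results, each a list with `field` and `weights`.
#' @export
simulate.shape_model <- function(object, nsim = 1, seed = 1, D_max = 3, ...) {
  lapply(seq_len(nsim), function(k)
    sample_deformation(object, D_max, rng_seed = seed + k - 1L))
}

#' Scree and variance-coverage plot for a shape model
#'
#' Left panel: eigenvalue spectrum (scree).  Right panel: cumulative
#' percentage of total variance against retained mode count, with the
#' `alpha` retention level and `T_hat` marked.
#'
#' @param x a `shape_model`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.shape_model <- function(x, ...) {
  lam <- x$eigenvalues
  if (!length(lam)) {
    warning("model has zero total variance; nothing to plot")
    return(invisible(x))
  }
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(seq_along(lam), lam, type = "b", log = "y",
       xlab = "mode", ylab = "eigenvalue (mm^2)", main = "Scree", ...)
  curve_pts <- mode_coverage_curve(lam)
  plot(curve_pts$modes, curve_pts$pct, type = "b", ylim = c(0, 100),
       xlab = "retained modes", ylab = "% of total variation",
       main = "Coverage", ...)
  abline(h = x$alpha, lty = 2)
  abline(v = x$T_hat, lty = 3)
  invisible(x)
}
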