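#' Assemble a training matrix from deformation vector fields
#'
#' Stacks `N >= 2` DVFs sharing one grid into the `3V x N` matrix whose
#' column `t` is the vectorized field `t`.  Vectorization is component-major
#' and frozen: the LR block, then the AP block, then the SI block, each
#' block in grid index order with the first (LR) axis fastest.
#' [devectorize_field()] is the exact inverse.
#'
#' @param dvfs list of [vector_field]s with identical grid geometry.
#' @return an object of class `training_matrix`: list with `columns`
#'   (numeric matrix), `n`, and `grid` (shape/spacing/origin).
#' @seealso [fit_shape_model()]
#' @export
build_training_matrix <- function(dvfs) {
  if (length(dvfs) < 2)
    stop("at least 2 DVFs are required (sample covariance divides by N - 1)",
         call. = FALSE)
  g1 <- dvfs[[1]]
  for (d in dvfs) {
    stopifnot(inherits(d, "vector_field"))
    stop_if_geometry_mismatch(g1, d, "training DVFs")
  }
  cols <- vapply(dvfs, vectorize_field, numeric(3 * prod(grid_shape(g1))))
  structure(list(columns = cols, n = length(dvfs),
                 grid = list(shape = grid_shape(g1), spacing = g1$spacing,
                             origin = g1$origin)),
            class = "training_matrix")
}

#' @rdname build_training_matrix
#' @param field a [vector_field] to vectorize.
#' @export
vectorize_field <- function(field) {
  c(as.vector(field$dx), as.vector(field$dy), as.vector(field$dz))
}

#' @rdname build_training_matrix
#' @param v numeric vector of length `3 * prod(grid$shape)`.
#' @param grid list with `shape`, `spacing`, `origin`.
#' @export
devectorize_field <- function(v, grid) {
  nv <- prod(grid$shape)
  stopifnot(length(v) == 3 * nv)
  vector_field(array(v[seq_len(nv)], grid$shape),
               array(v[nv + seq_len(nv)], grid$shape),
               array(v[2 * nv + seq_len(nv)], grid$shape),
               grid$spacing, grid$origin)
}

#' Fit an active shape model of deformation to training DVFs
#'
#' Learns the mean deformation and the principal modes of variation of a set
#' of deformation vector fields by PCA of their sample covariance
#' \deqn{\Sigma = \frac{1}{N-1}\sum_t (d_t - \bar d)(d_t - \bar d)^T.}
#' \eqn{\Sigma} (dimension `3V x 3V`) is never materialized: eigenpairs are
#' obtained from the `N x N` Gram matrix \eqn{G = C^T C/(N-1)} of the
#' centered columns \eqn{C}, whose nonzero eigenvalues equal those of
#' \eqn{\Sigma}, with covariance eigenvectors \eqn{\phi = C w / \|C w\|}.
#' Eigenvalues are sorted descending; values below `1e-12 * lambda_1` are
#' treated as zero (numerical rank of an N-sample Gram matrix).  Each mode's
#' sign is fixed by making its largest-magnitude entry positive, so results
#' do not depend on the linear-algebra backend.
#'
#' The retained count \eqn{\hat T} is the smallest number of leading modes
#' whose eigenvalue sum reaches `alpha` percent of the total variance (see
#' [select_principal_modes()]).  All nonzero eigenpairs are stored;
#' \eqn{\hat T} marks the cut used when sampling.
#'
#' @param D a `training_matrix` from [build_training_matrix()], or a list of
#'   [vector_field]s.
#' @param alpha retention level in `(0, 100]`: percentage of total variance
#'   the retained modes must reach.
#' @return an object of class `shape_model` with components `mean`
#'   (vectorized mean deformation), `eigenvalues` (all nonzero, descending),
#'   `modes` (orthonormal columns), `T_hat`, `alpha`, `total_variance`,
#'   `grid`, `n_train`.
#' @examples
#' z <- array(0, c(4, 4, 4)); o <- array(1, c(4, 4, 4))
#' m <- fit_shape_model(list(vector_field(o, z, z), vector_field(-o, z, z)),
#'                      alpha = 90)
#' m$T_hat  # 1
#' @export
fit_shape_model <- function(D, alpha = 90) {
  if (!inherits(D, "training_matrix")) D <- build_training_matrix(D)
  stopifnot(alpha > 0, alpha <= 100)
  C <- D$columns
  if (!all(is.finite(C)))
    stop("non-finite entries in training DVFs", call. = FALSE)
  n <- D$n
  mu <- rowMeans(C)
  C <- C - mu
  G <- crossprod(C) / (n - 1)
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  lam[lam < 0] <- 0
  if (lam[1] > 0) lam[lam < 1e-12 * lam[1]] <- 0
  keep <- which(lam > 0)
  if (length(keep)) {
    Phi <- C %*% eg$vectors[, keep, drop = FALSE]
    nrm <- sqrt(colSums(Phi^2))
    Phi <- sweep(Phi, 2, nrm, "/")
    # deterministic sign: largest-magnitude entry positive
    for (j in seq_len(ncol(Phi))) {
      k <- which.max(abs(Phi[, j]))
      if (Phi[k, j] < 0) Phi[, j] <- -Phi[, j]
    }
    lam_keep <- lam[keep]
  } else {
    Phi <- matrix(0, nrow(D$columns), 0)
    lam_keep <- numeric(0)
  }
  total <- sum(lam_keep)
  T_hat <- select_principal_modes(lam_keep, alpha)
  structure(list(mean = mu, eigenvalues = lam_keep, modes = Phi,
                 T_hat = T_hat, alpha = alpha, total_variance = total,
                 grid = D$grid, n_train = n),
            class = "shape_model")
}

#' Minimal number of modes reaching a retention level
#'
#' Returns the smallest \eqn{\hat T} such that the leading \eqn{\hat T}
#' eigenvalues sum to at least `alpha` percent of the total; 0 when the
#' total variance is 0.
#'
#' @param eigenvalues non-negative eigenvalues sorted descending.
#' @param alpha retention level in `(0, 100]`.
#' @return integer mode count.
#' @examples
#' select_principal_modes(c(4, 3, 2, 1), 90)  # 3
#' @export
select_principal_modes <- function(eigenvalues, alpha) {
  stopifnot(alpha > 0, alpha <= 100)
  if (!length(eigenvalues)) return(0L)
  if (any(eigenvalues < 0))
    stop("contract error: eigenvalues must be non-negative", call. = FALSE)
  if (is.unsorted(rev(eigenvalues), strictly = FALSE))
    stop("contract error: eigenvalues must be sorted descending",
         call. = FALSE)
  total <- sum(eigenvalues)
  if (total == 0) return(0L)
  hit <- which(cumsum(eigenvalues) >= (alpha / 100) * total)
  # the full sum always qualifies; guard the last-bit case where cumsum's
  # final entry differs from sum() by one rounding step
  if (!length(hit)) length(eigenvalues) else hit[1]
}

#' Variation-space reduction
#'
#' The efficiency of the compact representation: the percentage of modes
#' discarded when truncating an `N`-mode variation space at `T_hat` retained
#' modes, `100 * (N - T_hat) / N`.
#'
#' @param N number of training DVFs (total mode count).
#' @param T_hat retained mode count, `0 <= T_hat <= N`.
#' @return percentage in `[0, 100]`.
#' @examples
#' round(space_reduction(11, 5))   # 55
#' round(space_reduction(396, 12)) # 97
#' @export
space_reduction <- function(N, T_hat) {
  stopifnot(N >= 1)
  if (T_hat > N || T_hat < 0)
    stop("T_hat must lie in [0, N]", call. = FALSE)
  100 * (N - T_hat) / N
}

#' Mahalanobis distance of a mode-weight vector
#'
#' `sqrt(sum(b_j^2 / lambda_j))` over modes with nonzero weight: the
#' covariance-scaled distance of a sampled deformation from the model mean.
#'
#' @param b numeric weight vector, or a `mode_weights` object.
#' @param eigenvalues eigenvalues matching `b` (taken from the weights
#'   object when omitted).
#' @return non-negative scalar.
#' @export
mahalanobis_distance <- function(b, eigenvalues = NULL) {
  if (inherits(b, "mode_weights")) {
    if (is.null(eigenvalues)) eigenvalues <- b$eigenvalues
    b <- b$b
  }
  stopifnot(length(b) == length(eigenvalues))
  nz <- b != 0
  if (any(nz & eigenvalues <= 0))
    stop("contract error: nonzero weight on a zero-variance mode",
         call. = FALSE)
  if (!any(nz)) return(0)
  sqrt(sum(b[nz]^2 / eigenvalues[nz]))
}

#' Sample a random deformation from an active shape model
#'
#' Draws mode weights \eqn{b_j} independently Gaussian with variance
#' \eqn{\lambda_j} for the retained modes, subject to the Mahalanobis bound
#' \eqn{\sum_j b_j^2/\lambda_j \le D_{max}^2}.  The bound is enforced by
#' rejection sampling of the whole weight vector, which preserves the
#' Gaussian shape inside the Mahalanobis ball (neither per-coordinate
#' clipping nor radial rescaling does).  If 1000 consecutive draws are
#' rejected (pathologically small `D_max` with many modes), the last draw is
#' radially rescaled onto the bound as a fallback.  The sampled deformation
#' is \eqn{d = \bar d + \sum_j b_j \phi_j}.
#'
#' `D_max = 0` returns the mean deformation with all-zero weights.  Fully
#' reproducible for a given `rng_seed`; the caller's RNG state is left
#' untouched.
#'
#' @param model a [shape_model][fit_shape_model()].
#' @param D_max maximum Mahalanobis distance (non-negative).
#' @param rng_seed integer seed.
#' @return list with `field` (a [vector_field]) and `weights` (a
#'   `mode_weights` object with `b`, `D_max`, `eigenvalues`,
#'   `mahalanobis`).
#' @seealso [simulate.shape_model()]
#' @export
sample_deformation <- function(model, D_max, rng_seed) {
  stopifnot(inherits(model, "shape_model"), D_max >= 0)
  t_hat <- model$T_hat
  lam <- model$eigenvalues[seq_len(t_hat)]
  b <- numeric(t_hat)
  if (t_hat > 0 && D_max > 0) {
    with_preserved_rng(rng_seed, {
      sdv <- sqrt(pmax(lam, 0))
      rejected <- 0L
      repeat {
        b <- rnorm(t_hat, 0, sdv)
        b[lam <= 0] <- 0
        dm <- mahalanobis_distance(b, lam)
        if (dm <= D_max) break
        rejected <- rejected + 1L
        if (rejected >= 1000L) {
          b <- b * (D_max / dm)
          break
        }
      }
    })
  }
  v <- model$mean
  if (t_hat > 0)
    v <- v + as.vector(model$modes[, seq_len(t_hat), drop = FALSE] %*% b)
  weights <- structure(list(b = b, D_max = D_max, eigenvalues = lam,
                            mahalanobis = mahalanobis_distance(b, lam)),
                       class = "mode_weights")
  list(field = devectorize_field(v, model$grid), weights = weights)
}

with_preserved_rng <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.mode_weights <- function(x, ...) {
  cat(sprintf("<mode_weights> %d modes, Mahalanobis %.3f (D_max %.3f)\n",
              length(x$b), x$mahalanobis, x$D_max))
  invisible(x)
}

#' Persist and reload a shape model
#'
#' A model is stored as a directory: `meta.json` (grid geometry, alpha,
#' T_hat, training size, eigenvalues, the frozen vectorization order and
#' creation provenance) plus little-endian float64 arrays `mean.bin`,
#' `modes.bin`, `eigenvalues.bin`.  The round trip is bit-exact.
#'
#' @param model a `shape_model`.
#' @param dir directory path (created if needed).
#' @return `read_shape_model()` the restored model; `write_shape_model()`
#'   the directory, invisibly.
#' @export
write_shape_model <- function(model, dir) {
  stopifnot(inherits(model, "shape_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    class = "shape_model",
    grid = list(shape = model$grid$shape, spacing = model$grid$spacing,
                origin = model$grid$origin),
    alpha = model$alpha, T_hat = model$T_hat, n_train = model$n_train,
    n_modes = ncol(model$modes), total_variance = model$total_variance,
    vectorization = "component-major (LR, AP, SI blocks), first axis fastest",
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("deformgen")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_f64 <- function(x, f) {
    con <- file(file.path(dir, f), "wb")
    on.exit(close(con))
    writeBin(as.double(x), con, size = 8, endian = "little")
  }
  write_f64(model$mean, "mean.bin")
  write_f64(model$modes, "modes.bin")
  write_f64(model$eigenvalues, "eigenvalues.bin")
  invisible(dir)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  read_f64 <- function(f, n) {
    con <- file(file.path(dir, f), "rb")
    on.exit(close(con))
    readBin(con, "double", n = n, size = 8, endian = "little")
  }
  grid <- list(shape = as.integer(meta$grid$shape),
               spacing = as.numeric(meta$grid$spacing),
               origin = as.numeric(meta$grid$origin))
  p <- 3 * prod(grid$shape)
  m <- meta$n_modes
  structure(list(mean = read_f64("mean.bin", p),
                 eigenvalues = read_f64("eigenvalues.bin", m),
                 modes = matrix(read_f64("modes.bin", p * m), p, m),
                 T_hat = as.integer(meta$T_hat), alpha = meta$alpha,
                 total_variance = meta$total_variance, grid = grid,
                 n_train = as.integer(meta$n_train)),
            class = "shape_model")
}
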