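#' Demons registration parameters
#'
#' Configuration for the multi-resolution symmetric-force demons engine.
#' Forces are computed from the gradients of both the fixed image and the
#' currently-warped moving image; the per-iteration update is smoothed with
#' `sigma_update` (fluid-like regularization) and the accumulated field with
#' `sigma_field` (diffusion-like regularization), both in mm.
#'
#' @param levels pyramid depth; level `l` is downsampled by
#'   `2^(levels - l)` (default 3: x4, x2, x1).
#' @param iterations_per_level integer vector, one entry per level,
#'   coarsest first.
#' @param sigma_update Gaussian sigma (mm at the finest level) applied to
#'   each update field.  Internally converted to voxel units once and held
#'   fixed across pyramid levels, so coarse levels regularize over
#'   proportionally larger physical extents (the standard multiresolution
#'   behaviour); this is what lets featureless regions inherit the motion of
#'   surrounding structure.
#' @param sigma_field Gaussian sigma (mm at the finest level, same
#'   voxel-unit convention) applied to the accumulated field.  This
#'   diffusion term both regularizes and fills in displacement across flat,
#'   low-gradient regions, so it should not be much below ~1.5 voxels.
#' @param intensity_scale normalization constant \eqn{\kappa} (1/mm) in the
#'   force denominator; `NULL` (default) uses the reciprocal of the mean
#'   voxel spacing at each pyramid level, which balances the gradient and
#'   intensity-difference terms dimensionally (the standard demons
#'   normalization).
#' @param step_cap maximum displacement (mm) added per voxel per iteration.
#' @return an object of class `demons_params`.
#' @export
demons_params <- function(levels = 3,
                          iterations_per_level = c(50, 30, 20),
                          sigma_update = 1.5,
                          sigma_field = 4.0,
                          intensity_scale = NULL,
                          step_cap = 2.0) {
  stopifnot(levels >= 1, length(iterations_per_level) == levels,
            all(iterations_per_level >= 1),
            sigma_update > 0, sigma_field > 0, step_cap > 0,
            is.null(intensity_scale) || intensity_scale > 0)
  structure(list(levels = as.integer(levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 sigma_update = sigma_update, sigma_field = sigma_field,
                 intensity_scale = intensity_scale, step_cap = step_cap),
            class = "demons_params")
}

#' @export
print.demons_params <- function(x, ...) {
  cat(sprintf(paste0("<demons_params> %d levels, iters (%s), ",
                     "sigma_update %g mm, sigma_field %g mm, step cap %g mm\n"),
              x$levels, paste(x$iterations_per_level, collapse = ", "),
              x$sigma_update, x$sigma_field, x$step_cap))
  invisible(x)
}

#' Deformable registration with a symmetric-force demons algorithm
#'
#' Iteratively estimates a deformation vector field `d` on the grid of
#' `fixed` such that `warp_volume(moving, d)` approximates `fixed`
#' (pull-back convention).  Per iteration, with \eqn{\tilde m} the currently
#' warped moving image, \eqn{f} the fixed image and \eqn{g = \nabla f +
#' \nabla\tilde m}:
#' \deqn{u = (f - \tilde m)\, g \, / \, (\|g\|^2 + \kappa^2 (f - \tilde m)^2)}
#' The update `u` is smoothed with `sigma_update`, its per-voxel magnitude
#' clipped at `step_cap`, added to the field, and the field is smoothed with
#' `sigma_field`.  A Gaussian image pyramid provides coarse-to-fine
#' estimation.  Intensities are clamped to \[−1000, 2000\] beforehand so
#' isolated extreme values (dental-artifact-like outliers) cannot dominate
#' the force term.  Fully deterministic: identical inputs give bit-identical
#' fields.
#'
#' @param fixed,moving [scalar_volume]s on the same grid geometry.
#' @param params a [demons_params] object.
#' @return a [vector_field] on the grid of `fixed`, mm displacements.
#' @export
demons_register <- function(fixed, moving, params = demons_params()) {
  stopifnot(inherits(fixed, "scalar_volume"), inherits(moving, "scalar_volume"))
  stop_if_geometry_mismatch(fixed, moving, "fixed and moving")
  if (!all(is.finite(fixed$data)) || !all(is.finite(moving$data)))
    stop("non-finite intensities in registration input", call. = FALSE)
  f0 <- clamp_intensity(fixed)
  m0 <- clamp_intensity(moving)

  # sigmas are specified in mm at the finest level and applied in voxel
  # units at every level
  sig_u_vox <- params$sigma_update / fixed$spacing
  sig_f_vox <- params$sigma_field / fixed$spacing

  field <- NULL
  for (lev in seq_len(params$levels)) {
    fac <- 2^(params$levels - lev)
    flev <- downsample_volume(f0, fac)
    mlev <- downsample_volume(m0, fac)
    field <- if (is.null(field)) {
      zero_field_like(flev)
    } else {
      resample_field_to(field, flev)
    }
    field <- demons_level(flev, mlev, field,
                          params$iterations_per_level[lev], params,
                          sig_u_vox, sig_f_vox)
  }
  field
}

clamp_intensity <- function(vol, lo = -1000, hi = 2000) {
  scalar_volume(pmin(pmax(vol$data, lo), hi), vol$spacing, vol$origin)
}

zero_field_like <- function(vol) {
  z <- array(0, grid_shape(vol))
  vector_field(z, z, z, vol$spacing, vol$origin)
}

downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  arr <- cpp_gauss3(vol$data, rep(factor / 2, 3))
  sh <- grid_shape(vol)
  ix <- seq(1, sh[1], by = factor)
  iy <- seq(1, sh[2], by = factor)
  iz <- seq(1, sh[3], by = factor)
  scalar_volume(arr[ix, iy, iz, drop = FALSE], vol$spacing * factor,
                vol$origin)
}

# Resample a (coarse) field onto the grid of `target`; displacement values
# (mm) are physical and unchanged.
resample_field_to <- function(field, target) {
  sht <- grid_shape(target)
  idx <- base_index_grids(sht)
  # world position of target voxel -> continuous index on field grid
  conv <- function(i, ax)
    ((i - 1) * target$spacing[ax] + target$origin[ax] -
       field$origin[ax]) / field$spacing[ax] + 1
  qx <- conv(idx$x, 1); qy <- conv(idx$y, 2); qz <- conv(idx$z, 3)
  comp <- function(a) {
    out <- cpp_sample3d(a, qx, qy, qz, 0, TRUE, FALSE)
    dim(out) <- sht
    out
  }
  vector_field(comp(field$dx), comp(field$dy), comp(field$dz),
               target$spacing, target$origin)
}

gradient3 <- function(arr, spacing) {
  sh <- dim(arr)
  g <- function(ax) {
    out <- array(0, sh)
    n <- sh[ax]
    if (n < 3) return(out)
    pick <- function(i) switch(ax, arr[i, , , drop = FALSE],
                               arr[, i, , drop = FALSE],
                               arr[, , i, drop = FALSE])
    assign_mid <- function(val) {
      i <- 2:(n - 1)
      switch(ax, out[i, , ] <<- val, out[, i, ] <<- val, out[, , i] <<- val)
    }
    assign_mid((pick(3:n) - pick(1:(n - 2))) / (2 * spacing[ax]))
    out
  }
  list(gx = g(1), gy = g(2), gz = g(3))
}

demons_level <- function(fixed, moving, field, iters, params,
                         sig_u, sig_f) {
  sp <- fixed$spacing
  f <- fixed$data
  gf <- gradient3(f, sp)
  # kappa in 1/mm balances the two denominator terms dimensionally
  # (|grad|^2 is HU^2/mm^2, kappa^2 diff^2 must match); 1/mean-spacing is
  # the standard demons normalization
  kappa <- params$intensity_scale %||% (1 / mean(sp))
  cap <- params$step_cap
  for (it in seq_len(iters)) {
    mw <- sample_field_at_scalar(moving, field)
    gm <- gradient3(mw, sp)
    diffI <- f - mw
    gx <- gf$gx + gm$gx; gy <- gf$gy + gm$gy; gz <- gf$gz + gm$gz
    den <- gx^2 + gy^2 + gz^2 + (kappa^2) * diffI^2
    scale <- diffI / den
    scale[!is.finite(scale)] <- 0
    ux <- cpp_gauss3(scale * gx, sig_u)
    uy <- cpp_gauss3(scale * gy, sig_u)
    uz <- cpp_gauss3(scale * gz, sig_u)
    mag <- sqrt(ux^2 + uy^2 + uz^2)
    if (any(mag > cap)) {
      sc <- pmin(1, cap / pmax(mag, 1e-300))
      ux <- ux * sc; uy <- uy * sc; uz <- uz * sc
    }
    dx <- cpp_gauss3(field$dx + ux, sig_f)
    dy <- cpp_gauss3(field$dy + uy, sig_f)
    dz <- cpp_gauss3(field$dz + uz, sig_f)
    field <- vector_field(dx, dy, dz, field$spacing, field$origin)
  }
  field
}

# warp `moving` by `field` with edge-clamped sampling, returning the raw array
sample_field_at_scalar <- function(moving, field) {
  sh <- grid_shape(moving)
  idx <- base_index_grids(sh)
  qx <- idx$x + as.vector(field$dx) / moving$spacing[1]
  qy <- idx$y + as.vector(field$dy) / moving$spacing[2]
  qz <- idx$z + as.vector(field$dz) / moving$spacing[3]
  out <- cpp_sample3d(moving$data, qx, qy, qz, 0, TRUE, FALSE)
  dim(out) <- sh
  out
}
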