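#' Iteratively invert a deformation vector field
#'
#' Computes the inverse `v` of a DVF `d` by the fixed-point iteration
#' `v[n+1](x) = -d(x + v[n](x))` starting from `v[0] = 0`, with trilinear,
#' edge-clamped sampling of `d`.  Iteration stops when the maximum per-voxel
#' change is below `tol` (in voxels) or after `max_iter` sweeps.  The result
#' carries the residual statistic `||d(x + v(x)) + v(x)||`: attributes
#' `residual_mean_vox` / `residual_max_vox` (voxel units) and `converged`.
#' If the maximum residual still exceeds `10 * tol` at `max_iter`, a warning
#' is emitted and `converged` is `FALSE`; the field is returned regardless.
#'
#' @param d a [vector_field].
#' @param tol convergence tolerance in voxels.
#' @param max_iter maximum number of fixed-point sweeps.
#' @return a [vector_field] (the inverse), with residual attributes.
#' @examples
#' z <- array(0, c(6, 6, 6))
#' inv <- invert_dvf(vector_field(z, z, z))
#' attr(inv, "residual_max_vox")  # 0
#' @export
invert_dvf <- function(d, tol = 0.01, max_iter = 50) {
  stopifnot(inherits(d, "vector_field"), tol > 0, max_iter >= 1)
  sp <- d$spacing
  v <- zero_field_like(d)
  for (it in seq_len(max_iter)) {
    s <- sample_field_at(d, v, clamp = TRUE)
    vx <- -s$dx; vy <- -s$dy; vz <- -s$dz
    dmax <- max(sqrt(((vx - v$dx) / sp[1])^2 + ((vy - v$dy) / sp[2])^2 +
                       ((vz - v$dz) / sp[3])^2))
    v <- vector_field(vx, vy, vz, sp, d$origin)
    if (dmax < tol) break
  }
  s <- sample_field_at(d, v, clamp = TRUE)
  res <- sqrt(((s$dx + v$dx) / sp[1])^2 + ((s$dy + v$dy) / sp[2])^2 +
                ((s$dz + v$dz) / sp[3])^2)
  attr(v, "residual_mean_vox") <- mean(res)
  attr(v, "residual_max_vox") <- max(res)
  attr(v, "converged") <- max(res) <= 10 * tol
  if (!attr(v, "converged"))
    warning("invert_dvf: residual ", signif(max(res), 3),
            " voxels above 10 * tol after ", max_iter, " iterations",
            call. = FALSE)
  v
}

#' Compose two deformation vector fields
#'
#' Returns `c` with `c(x) = b(x) + a(x + b(x))` (trilinear, edge-clamped
#' sampling of `a`), so that pull-back warping by `c` equals warping by `b`
#' followed by warping by `a`:
#' `warp_volume(vol, compose_dvfs(a, b)) ~ warp_volume(warp_volume(vol, a), b)`.
#'
#' @param a,b [vector_field]s on the same grid geometry.
#' @return a [vector_field].
#' @export
compose_dvfs <- function(a, b) {
  stopifnot(inherits(a, "vector_field"), inherits(b, "vector_field"))
  stop_if_geometry_mismatch(a, b, "composed fields")
  s <- sample_field_at(a, b, clamp = TRUE)
  vector_field(b$dx + s$dx, b$dy + s$dy, b$dz + s$dz, a$spacing, a$origin)
}

#' Transfer an intra-patient DVF through an inter-patient DVF
#'
#' Moves a DVF expressed in one subject's planning space into the reference
#' space: each displacement component of `intra` is treated as a scalar 3D
#' image and resampled through `inter` exactly as [warp_volume()] resamples
#' a scalar volume (trilinear, out-of-grid samples 0):
#' `out_c(y) = intra_c(y + inter(y))`.
#' The vector components are deliberately NOT reoriented (no Jacobian
#' applied): the transfer is a per-component image resampling, trading
#' differential-geometric correctness for a simple, invertible-by-resampling
#' mapping of the magnitude images.
#'
#' @param intra the intra-patient [vector_field] (subject planning space).
#' @param inter the inter-patient [vector_field] mapping reference-grid
#'   points into the subject space.
#' @return a [vector_field] on the reference grid.
#' @export
transfer_dvf <- function(intra, inter) {
  stopifnot(inherits(intra, "vector_field"), inherits(inter, "vector_field"))
  stop_if_geometry_mismatch(intra, inter, "transferred fields")
  sample_field_at(intra, inter, clamp = FALSE, fill = 0)
}
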