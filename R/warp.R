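#' Warp a volume by a deformation vector field
#'
#' Pull-back warping: the output at grid point `x` samples the input volume
#' at world point `x + dvf(x)`, so the DVF obtained by registering a moving
#' image to a fixed image (fixed grid) warps the moving image onto the fixed
#' grid.  Displacements are in mm and converted to (possibly anisotropic)
#' voxel offsets using the grid spacing.  Samples falling outside the grid
#' take `fill`; the default −1000 is air for CT-like volumes (use 0 and
#' `mode = "nearest"` for masks).
#'
#' @param vol a [scalar_volume] (or [label_mask]; see [warp_mask()]).
#' @param dvf a [vector_field] on the same grid geometry as `vol`.
#' @param mode `"linear"` (trilinear) or `"nearest"`; nearest is for label
#'   images.
#' @param fill intensity assigned to out-of-grid samples.
#' @param mask a [label_mask] to warp with nearest-neighbour sampling and
#'   fill 0.
#' @return a [scalar_volume] (resp. [label_mask]) on the grid of `vol`.
#' @examples
#' v <- scalar_volume(array(rnorm(4^3), c(4, 4, 4)))
#' z <- vector_field(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
#'                   array(0, c(4, 4, 4)))
#' stopifnot(identical(warp_volume(v, z)$data, v$data))
#' @export
warp_volume <- function(vol, dvf, mode = c("linear", "nearest"),
                        fill = -1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, c("scalar_volume", "label_mask")),
            inherits(dvf, "vector_field"))
  stop_if_geometry_mismatch(vol, dvf, "volume and DVF")
  sh <- grid_shape(vol)
  idx <- base_index_grids(sh)
  qx <- idx$x + as.vector(dvf$dx) / vol$spacing[1]
  qy <- idx$y + as.vector(dvf$dy) / vol$spacing[2]
  qz <- idx$z + as.vector(dvf$dz) / vol$spacing[3]
  out <- cpp_sample3d(vol$data, qx, qy, qz, fill, FALSE,
                      mode == "nearest")
  dim(out) <- sh
  scalar_volume(out, vol$spacing, vol$origin)
}

#' @rdname warp_volume
#' @export
warp_mask <- function(mask, dvf) {
  stopifnot(inherits(mask, "label_mask"))
  out <- warp_volume(scalar_volume(mask$data, mask$spacing, mask$origin),
                     dvf, mode = "nearest", fill = 0)
  label_mask(out$data, mask$label_names, mask$spacing, mask$origin)
}

# 1-based voxel index grids as long vectors, column-major (LR fastest)
base_index_grids <- function(sh) {
  list(x = rep.int(seq_len(sh[1]), sh[2] * sh[3]),
       y = rep.int(rep(seq_len(sh[2]), each = sh[1]), sh[3]),
       z = rep(seq_len(sh[3]), each = sh[1] * sh[2]))
}

# Sample each component of `field` at voxel positions displaced by `by`
# (both on the same grid); clamp or fill handling selectable.
sample_field_at <- function(field, by, clamp = TRUE, fill = 0) {
  sh <- grid_shape(field)
  idx <- base_index_grids(sh)
  qx <- idx$x + as.vector(by$dx) / field$spacing[1]
  qy <- idx$y + as.vector(by$dy) / field$spacing[2]
  qz <- idx$z + as.vector(by$dz) / field$spacing[3]
  comp <- function(a) {
    out <- cpp_sample3d(a, qx, qy, qz, fill, clamp, FALSE)
    dim(out) <- sh
    out
  }
  vector_field(comp(field$dx), comp(field$dy), comp(field$dz),
               field$spacing, field$origin)
}

# Gaussian-smooth a 3D array with per-axis sigma given in mm.
smooth_mm <- function(arr, sigma_mm, spacing) {
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3)
  cpp_gauss3(arr, sigma_mm / spacing)
}
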