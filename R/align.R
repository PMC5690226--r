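#' Rigid (translation-only) pre-alignment by cross-correlation
#'
#' Exhaustively searches integer voxel translations within `search_radius`
#' and returns the translation of `moving` that maximizes the normalized
#' cross-correlation (NCC) with `fixed` over the overlap region.  Ties are
#' broken toward the smaller translation magnitude, then lexicographically.
#' Translation-only: sub-voxel and rotational residuals are left to the
#' deformable registration step.
#'
#' @param moving,fixed [scalar_volume]s with identical spacing.
#' @param search_radius maximum |shift| per axis, voxels.
#' @param min_overlap minimum number of overlapping voxels for a candidate
#'   shift to be admissible.
#' @return integer length-3 translation `t` (voxels): shifting `moving` by
#'   `t` (content moved toward larger indices for positive `t`) best aligns
#'   it with `fixed`.
#' @examples
#' a <- scalar_volume(array(rnorm(10^3), c(10, 10, 10)))
#' rigid_align(a, a, search_radius = 2)  # (0, 0, 0)
#' @export
rigid_align <- function(moving, fixed, search_radius = 5, min_overlap = 8) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(fixed, "scalar_volume"))
  if (max(abs(moving$spacing - fixed$spacing)) > 1e-6)
    stop("rigid_align requires identical spacing", call. = FALSE)
  r <- as.integer(search_radius)
  shm <- grid_shape(moving); shf <- grid_shape(fixed)
  best <- NULL
  cand <- expand.grid(tx = -r:r, ty = -r:r, tz = -r:r)
  # deterministic tie-breaking: smaller |t|, then lexicographic
  ord <- order(cand$tx^2 + cand$ty^2 + cand$tz^2, cand$tx, cand$ty, cand$tz)
  cand <- cand[ord, ]
  best_ncc <- -Inf; best_t <- NULL
  for (k in seq_len(nrow(cand))) {
    t <- c(cand$tx[k], cand$ty[k], cand$tz[k])
    # moving voxel i maps to fixed frame index i + t
    lof <- pmax(1L, 1L + t); hif <- pmin(shf, shm + t)
    if (any(hif - lof < 0)) next
    lom <- lof - t; him <- hif - t
    mv <- moving$data[lom[1]:him[1], lom[2]:him[2], lom[3]:him[3]]
    fv <- fixed$data[lof[1]:hif[1], lof[2]:hif[2], lof[3]:hif[3]]
    if (length(mv) < min_overlap) next
    sm <- sd(mv); sf <- sd(fv)
    ncc <- if (sm < 1e-12 || sf < 1e-12) {
      if (sm < 1e-12 && sf < 1e-12) 1 else 0
    } else {
      mean((mv - mean(mv)) * (fv - mean(fv))) / (sm * sf) *
        length(mv) / (length(mv) - 1)
    }
    if (ncc > best_ncc + 1e-12) {
      best_ncc <- ncc; best_t <- t
    }
  }
  if (is.null(best_t))
    stop("alignment error: no candidate shift produced a usable overlap",
         call. = FALSE)
  as.integer(best_t)
}

#' Crop aligned volumes to their common space
#'
#' Given per-volume integer translations into a common reference frame
#' (e.g. from [rigid_align()]), crops every volume to the intersection
#' bounding box of the aligned grids, so all outputs share one grid
#' geometry.  Voxel contents are preserved (pure cropping, no resampling).
#'
#' @param volumes list of [scalar_volume]s sharing one spacing.
#' @param translations list of integer length-3 translations mapping each
#'   volume into the reference frame (volume voxel `i` lands at reference
#'   index `i + t`).
#' @return list of cropped [scalar_volume]s with identical geometry.
#' @export
crop_to_common_space <- function(volumes, translations) {
  stopifnot(length(volumes) >= 1, length(volumes) == length(translations))
  sp <- volumes[[1]]$spacing
  for (v in volumes)
    if (max(abs(v$spacing - sp)) > 1e-6)
      stop("crop_to_common_space requires identical spacing", call. = FALSE)
  lo <- rep(-Inf, 3); hi <- rep(Inf, 3)
  for (k in seq_along(volumes)) {
    t <- as.integer(translations[[k]])
    lo <- pmax(lo, 1 + t)
    hi <- pmin(hi, grid_shape(volumes[[k]]) + t)
  }
  if (any(hi - lo < 0))
    stop("geometry error: aligned volumes have empty intersection",
         call. = FALSE)
  origin0 <- volumes[[1]]$origin +
    (lo - 1 - as.integer(translations[[1]])) * sp
  lapply(seq_along(volumes), function(k) {
    t <- as.integer(translations[[k]])
    lom <- lo - t; him <- hi - t
    scalar_volume(volumes[[k]]$data[lom[1]:him[1], lom[2]:him[2],
                                    lom[3]:him[3], drop = FALSE],
                  sp, origin0)
  })
}

#' Crop a grid object to the geometry of a cropped companion
#'
#' After [crop_to_common_space()], companion objects (masks, ground-truth
#' fields, latent basis fields) still live on the original grid.
#' `crop_like()` extracts the index window of `x` that matches the geometry
#' of `target`, using the origin difference (which must be an integer
#' number of voxels).
#'
#' @param x a [scalar_volume], [label_mask] or [vector_field].
#' @param target object carrying the target geometry.
#' @return `x` cropped to the geometry of `target`.
#' @export
crop_like <- function(x, target) {
  if (same_geometry(x, target)) return(x)
  sp <- x$spacing
  if (max(abs(sp - target$spacing)) > 1e-6)
    stop("geometry error: spacing mismatch in crop_like", call. = FALSE)
  off <- (target$origin - x$origin) / sp
  if (max(abs(off - round(off))) > 1e-6)
    stop("geometry error: origins differ by a non-integer voxel offset",
         call. = FALSE)
  off <- as.integer(round(off))
  sht <- grid_shape(target)
  shx <- grid_shape(x)
  if (any(off < 0) || any(off + sht > shx))
    stop("geometry error: target window lies outside the source grid",
         call. = FALSE)
  ix <- off[1] + seq_len(sht[1])
  iy <- off[2] + seq_len(sht[2])
  iz <- off[3] + seq_len(sht[3])
  if (inherits(x, "vector_field")) {
    vector_field(x$dx[ix, iy, iz, drop = FALSE],
                 x$dy[ix, iy, iz, drop = FALSE],
                 x$dz[ix, iy, iz, drop = FALSE],
                 target$spacing, target$origin)
  } else if (inherits(x, "label_mask")) {
    label_mask(x$data[ix, iy, iz, drop = FALSE], x$label_names,
               target$spacing, target$origin)
  } else {
    scalar_volume(x$data[ix, iy, iz, drop = FALSE],
                  target$spacing, target$origin)
  }
}
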