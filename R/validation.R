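#' Voxel-wise registration error map
#'
#' Subtracts the two fields component-wise (LR, AP, SI) and returns the
#' per-voxel Euclidean magnitude of the difference in mm — the voxel-level
#' registration error when `computed` is a DIR result and `truth` the known
#' deformation.
#'
#' @param computed,truth [vector_field]s on the same grid geometry.
#' @return a [scalar_volume] of errors (mm).
#' @export
error_map <- function(computed, truth) {
  stopifnot(inherits(computed, "vector_field"), inherits(truth, "vector_field"))
  stop_if_geometry_mismatch(computed, truth, "compared fields")
  scalar_volume(sqrt((computed$dx - truth$dx)^2 +
                       (computed$dy - truth$dy)^2 +
                       (computed$dz - truth$dz)^2),
                computed$spacing, computed$origin)
}

#' Per-structure statistics of a scalar map
#'
#' Mean, SD (N−1 denominator), max and voxel count of `map` over the voxels
#' carrying `label` in `mask`.
#'
#' @param map a [scalar_volume] (e.g. an [error_map()]).
#' @param mask a [label_mask] on the same geometry.
#' @param label integer label to evaluate.
#' @return named numeric: `mean`, `sd`, `max`, `n`.
#' @export
structure_stats <- function(map, mask, label) {
  stopifnot(inherits(map, "scalar_volume"), inherits(mask, "label_mask"))
  stop_if_geometry_mismatch(map, mask, "map and mask")
  sel <- mask$data == as.integer(label)
  if (!any(sel))
    stop("label ", label, " is empty in the mask", call. = FALSE)
  v <- map$data[sel]
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, max = max(v),
    n = length(v))
}

#' Mean deformation magnitude inside a structure
#'
#' Mean and SD (mm) of the displacement magnitude of `dvf` over the voxels
#' carrying `label`.
#'
#' @param dvf a [vector_field].
#' @inheritParams structure_stats
#' @return named numeric: `mean`, `sd`.
#' @export
mean_deformation_magnitude <- function(dvf, mask, label) {
  s <- structure_stats(field_magnitude(dvf), mask, label)
  s[c("mean", "sd")]
}

#' Dice similarity coefficient
#'
#' Volumetric overlap `100 * 2|A ∩ B| / (|A| + |B|)` in percent between the
#' voxels carrying `label_a` in `a` and `label_b` in `b`.  Two empty masks
#' are an error (the metric is undefined and silence would hide a data
#' problem).
#'
#' @param a,b [label_mask]s on the same geometry.
#' @param label_a,label_b labels to compare (default 1; `label_b` defaults
#'   to `label_a`).
#' @return percentage in `[0, 100]`.
#' @export
dice <- function(a, b, label_a = 1, label_b = label_a) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  stop_if_geometry_mismatch(a, b, "masks")
  A <- a$data == as.integer(label_a)
  B <- b$data == as.integer(label_b)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0)
    stop("undefined metric: both masks are empty", call. = FALSE)
  100 * 2 * sum(A & B) / (na + nb)
}

#' Mean surface distance
#'
#' Surface voxels are labeled voxels with at least one six-connected
#' unlabeled neighbour (grid-edge voxels count their missing neighbours as
#' unlabeled).  Returns the symmetric average of the two directed mean
#' nearest-surface distances (A→B and B→A) in mm, using the anisotropic
#' voxel spacing.
#'
#' @inheritParams dice
#' @return mean surface distance (mm).
#' @export
mean_surface_distance <- function(a, b, label_a = 1, label_b = label_a) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  stop_if_geometry_mismatch(a, b, "masks")
  sa <- surface_coords(a$data == as.integer(label_a), a$spacing)
  sb <- surface_coords(b$data == as.integer(label_b), b$spacing)
  if (nrow(sa) == 0 || nrow(sb) == 0)
    stop("undefined metric: empty mask", call. = FALSE)
  (directed_mean_dist(sa, sb) + directed_mean_dist(sb, sa)) / 2
}

# world coordinates (mm) of the 6-connectivity surface voxels of `sel`
surface_coords <- function(sel, spacing) {
  sh <- dim(sel)
  interior <- array(TRUE, sh)
  shift_and <- function(acc, ax, dir) {
    n <- sh[ax]
    nb <- array(FALSE, sh)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    switch(ax,
           nb[dst, , ] <- sel[src, , ],
           nb[, dst, ] <- sel[, src, ],
           nb[, , dst] <- sel[, , src])
    acc & nb
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, ax, dir)
  surf <- which(sel & !interior, arr.ind = TRUE)
  cbind((surf[, 1] - 1) * spacing[1],
        (surf[, 2] - 1) * spacing[2],
        (surf[, 3] - 1) * spacing[3])
}

# mean over rows of `from` of the nearest-neighbour distance into `to`
directed_mean_dist <- function(from, to, chunk = 512L) {
  n <- nrow(from)
  tot <- 0
  to_sq <- rowSums(to^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    blk <- from[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), to_sq, "+") - 2 * tcrossprod(blk, to)
    tot <- tot + sum(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  tot / n
}

#' Cumulative variance coverage of the principal modes
#'
#' Point `k` is the percentage of the total variation represented by the
#' leading `k` modes, `100 * sum(lambda[1:k]) / sum(lambda)`.  The curve is
#' non-decreasing and ends at 100.
#'
#' @param eigenvalues non-negative eigenvalues sorted descending, with
#'   positive total.
#' @return data frame with columns `modes` and `pct`.
#' @export
mode_coverage_curve <- function(eigenvalues) {
  if (!length(eigenvalues) || sum(eigenvalues) <= 0)
    stop("mode coverage undefined for zero total variance", call. = FALSE)
  if (is.unsorted(rev(eigenvalues)))
    stop("contract error: eigenvalues must be sorted descending",
         call. = FALSE)
  data.frame(modes = seq_along(eigenvalues),
             pct = 100 * cumsum(eigenvalues) / sum(eigenvalues))
}

#' Fractional mode count reaching a coverage target, by interpolation
#'
#' Linearly interpolates the [mode_coverage_curve()] to find the (possibly
#' fractional) number of principal modes at which `target_percent` of the
#' total variation is reached.  Below the first curve point the segment
#' from `(0, 0)` to `(1, pct_1)` is used; a target hitting a curve point
#' exactly returns that integer.
#'
#' @param curve data frame from [mode_coverage_curve()] (columns `modes`,
#'   `pct`).
#' @param target_percent coverage target in `(0, 100]`.
#' @return fractional mode count.
#' @examples
#' crv <- data.frame(modes = c(4, 5), pct = c(88, 91))
#' modes_needed_interpolated(crv, 90)  # 4.666...
#' @export
modes_needed_interpolated <- function(curve, target_percent) {
  stopifnot(is.data.frame(curve), all(c("modes", "pct") %in% names(curve)),
            target_percent <= 100)
  if (target_percent > max(curve$pct) + 1e-9)
    stop("target above the curve maximum (", signif(max(curve$pct), 4),
         "%)", call. = FALSE)
  m <- c(0, curve$modes)
  p <- c(0, curve$pct)
  hit <- which(p >= target_percent - 1e-12)[1]
  if (abs(p[hit] - target_percent) <= 1e-12) return(m[hit])
  m[hit - 1] + (target_percent - p[hit - 1]) / (p[hit] - p[hit - 1]) *
    (m[hit] - m[hit - 1])
}

#' Modes needed versus training-set size
#'
#' For each requested subset size, fits a shape model on a seeded random
#' subset of the training DVFs and reports the interpolated number of modes
#' needed to reach `alpha` percent of that subset's total variation.
#'
#' @param dvfs list of [vector_field]s.
#' @param alpha coverage target (percent).
#' @param subset_sizes integer sizes, each `>= 2` and `<=` the number of
#'   DVFs; a size equal to the full set uses all DVFs (no resampling).
#' @param seed integer seed controlling the subset draws.
#' @return data frame with columns `n_dvfs` and `modes_needed`.
#' @export
modes_vs_training_size <- function(dvfs, alpha = 90, subset_sizes, seed = 1) {
  n <- length(dvfs)
  stopifnot(all(subset_sizes >= 2), all(subset_sizes <= n))
  res <- numeric(length(subset_sizes))
  with_preserved_rng(seed, {
    for (k in seq_along(subset_sizes)) {
      sz <- subset_sizes[k]
      idx <- if (sz == n) seq_len(n) else sort(sample.int(n, sz))
      fit <- fit_shape_model(dvfs[idx], alpha = alpha)
      res[k] <- modes_needed_interpolated(
        mode_coverage_curve(fit$eigenvalues), alpha)
    }
  })
  data.frame(n_dvfs = as.integer(subset_sizes), modes_needed = res)
}
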