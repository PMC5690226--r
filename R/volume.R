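#' Volumetric containers
#'
#' `scalar_volume()`, `vector_field()` and `label_mask()` wrap dense 3D grids
#' with the axis-aligned geometry used throughout the package.  Grids are
#' indexed `(LR, AP, SI)` (left-right, anterior-posterior, superior-inferior);
#' the world coordinate (mm) of 1-based voxel index `i` along an axis is
#' `origin + (i - 1) * spacing`.  No rotation/direction matrix is supported:
#' clinical head-and-neck CT in this workflow is resampled axis-aligned, and
#' keeping grids axis-aligned keeps the displacement-field algebra
#' unambiguous.
#'
#' Displacements in a [vector_field] are stored in millimetres (physical
#' units, not voxels) because clinical CT spacing is anisotropic.
#'
#' @param data 3D numeric array of intensities (HU-like) or integer labels.
#' @param dx,dy,dz 3D numeric arrays of displacement (mm) along LR, AP, SI.
#' @param spacing numeric length-3, mm per voxel, all `> 0`.
#' @param origin numeric length-3, world position (mm) of voxel `(1,1,1)`.
#' @param label_names named list or character vector mapping label integers
#'   (as names) to structure names, e.g. `list("1" = "body")`.
#' @return An object of class `scalar_volume`, `vector_field` or
#'   `label_mask`.
#' @examples
#' v <- scalar_volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 2.5))
#' v
#' f <- vector_field(array(1, c(4, 4, 4)), array(-2, c(4, 4, 4)),
#'                   array(3, c(4, 4, 4)))
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_grid3d(data)
  geom <- check_geometry(dim(data), spacing, origin)
  structure(list(data = data, spacing = geom$spacing, origin = geom$origin),
            class = "scalar_volume")
}

#' @rdname scalar_volume
#' @export
vector_field <- function(dx, dy, dz, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dx <- as_grid3d(dx); dy <- as_grid3d(dy); dz <- as_grid3d(dz)
  if (!identical(dim(dx), dim(dy)) || !identical(dim(dx), dim(dz)))
    stop("geometry mismatch: dx, dy, dz must share one grid", call. = FALSE)
  if (!all(is.finite(dx)) || !all(is.finite(dy)) || !all(is.finite(dz)))
    stop("vector field contains non-finite displacements", call. = FALSE)
  geom <- check_geometry(dim(dx), spacing, origin)
  structure(list(dx = dx, dy = dy, dz = dz,
                 spacing = geom$spacing, origin = geom$origin),
            class = "vector_field")
}

#' @rdname scalar_volume
#' @export
label_mask <- function(data, label_names = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  data <- as_grid3d(data)
  if (any(data < 0) || any(data != round(data)))
    stop("label mask must contain non-negative integers", call. = FALSE)
  storage.mode(data) <- "integer"
  geom <- check_geometry(dim(data), spacing, origin)
  used <- setdiff(sort(unique(as.vector(data))), 0L)
  if (is.null(label_names))
    label_names <- setNames(as.list(paste0("label_", used)), as.character(used))
  label_names <- as.list(label_names)
  missing <- setdiff(as.character(used), names(label_names))
  if (length(missing))
    stop("labels used in data but absent from label_names: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(data = data, label_names = label_names,
                 spacing = geom$spacing, origin = geom$origin),
            class = "label_mask")
}

as_grid3d <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("data must be a 3D array", call. = FALSE)
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  storage.mode(x) <- "double"
  x
}

check_geometry <- function(shape, spacing, origin) {
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  if (any(shape < 1))
    stop("grid shape must be positive", call. = FALSE)
  list(spacing = spacing, origin = origin)
}

#' Grid geometry helpers
#'
#' @param x a `scalar_volume`, `vector_field` or `label_mask`.
#' @param a,b two grid objects to compare.
#' @return `grid_shape()` the integer dimensions; `same_geometry()` a logical.
#' @export
grid_shape <- function(x) {
  dim(if (inherits(x, "vector_field")) x$dx else x$data)
}

#' @rdname grid_shape
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(grid_shape(a), grid_shape(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop("geometry mismatch: ", what, " must share one grid geometry",
         call. = FALSE)
  invisible(TRUE)
}

#' Per-voxel magnitude of a vector field
#'
#' Euclidean norm `sqrt(dx^2 + dy^2 + dz^2)` in mm, returned as a
#' [scalar_volume] on the same grid.
#'
#' @param field a [vector_field].
#' @return a [scalar_volume] of magnitudes (mm).
#' @export
field_magnitude <- function(field) {
  stopifnot(inherits(field, "vector_field"))
  scalar_volume(sqrt(field$dx^2 + field$dy^2 + field$dz^2),
                field$spacing, field$origin)
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.vector_field <- function(x, ...) {
  d <- dim(x$dx)
  m <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  cat(sprintf("<vector_field> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  |d| mean %.3g mm, max %.3g mm\n", mean(m), max(m)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  for (l in names(x$label_names))
    cat(sprintf("  %s: %s (%d voxels)\n", l, x$label_names[[l]],
                sum(x$data == as.integer(l))))
  invisible(x)
}
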