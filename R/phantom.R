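#' Specification of a synthetic head-and-neck-like phantom
#'
#' Geometric stand-in for a head-and-neck CT: a soft-tissue body ellipsoid
#' (~0 HU) in air (−1000 HU) containing a bone-like mandible arc (+1000 HU)
#' and two low-contrast parotid-like ellipsoids (+40 HU), with additive
#' Gaussian noise.  Structure positions/radii are in mm relative to the grid
#' center.  The defaults give a 128 x 128 x 144 mm volume at clinical-like
#' anisotropic spacing, big enough for a 3-level registration pyramid and
#' small enough for seconds-scale registration.
#'
#' @param shape grid size (voxels), default `c(64, 64, 48)`.
#' @param spacing voxel size mm, default `c(2, 2, 3)`.
#' @param body_radii body ellipsoid radii (mm).
#' @param mandible list: `center_offset` (mm, from grid center),
#'   `arc_radius` (mm), `tube_radius` (mm), `half_angle` (degrees; arc spans
#'   the anterior direction +/- this angle).
#' @param parotid list: `offset_lr` (mm, lateral distance of each gland),
#'   `offset_ap`, `offset_si` (mm), `radii` (mm).
#' @param spine list: `offset_ap` (mm, posterior offset) and `radius` (mm)
#'   of a vertical bone-like column spanning the body (labelled as body in
#'   the mask; it exists to give the interior the kind of high-contrast
#'   landmark real CT has).
#' @param intensities HU values for `air`, `body`, `bone`, `parotid`.
#' @param noise_sd additive Gaussian noise SD (HU).
#' @param texture_amplitude amplitude (HU) of a smooth, deterministic
#'   soft-tissue intensity modulation added inside the body (0 = uniform
#'   soft tissue).  Real CT soft tissue is not flat; without some
#'   large-scale intensity structure an intensity-driven registration has
#'   nothing to anchor interior voxels to.
#' @param seed integer seed for the noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(2, 2, 3),
                         body_radii = c(48, 44, 60),
                         mandible = list(center_offset = c(0, -8, -24),
                                         arc_radius = 26, tube_radius = 6,
                                         half_angle = 70),
                         parotid = list(offset_lr = 32, offset_ap = 2,
                                        offset_si = -16,
                                        radii = c(10, 14, 18)),
                         spine = list(offset_ap = 22, radius = 7),
                         intensities = c(air = -1000, body = 0, bone = 1000,
                                         parotid = 40),
                         noise_sd = 10, texture_amplitude = 0, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 8), all(spacing > 0),
            all(body_radii > 0), noise_sd >= 0)
  if (any(intensities < -1000) || any(intensities > 2000))
    stop("spec error: intensities must lie in [-1000, 2000]", call. = FALSE)
  sp <- structure(list(shape = as.integer(shape), spacing = spacing,
                       body_radii = body_radii, mandible = mandible,
                       parotid = parotid, spine = spine,
                       intensities = intensities, noise_sd = noise_sd,
                       texture_amplitude = texture_amplitude,
                       seed = as.integer(seed)),
                  class = "phantom_spec")
  check_structures_fit(sp)
  sp
}

check_structures_fit <- function(spec) {
  # every structure must fit inside the body ellipsoid
  m <- spec$mandible
  reach_m <- sqrt(sum(m$center_offset^2)) + m$arc_radius + m$tube_radius
  p <- spec$parotid
  reach_p <- sqrt(p$offset_lr^2 + p$offset_ap^2 + p$offset_si^2) +
    max(p$radii)
  if (reach_m > max(spec$body_radii) || reach_p > max(spec$body_radii))
    stop("spec error: structures exceed the body ellipsoid", call. = FALSE)
  half_extent <- (spec$shape - 1) * spec$spacing / 2
  if (any(spec$body_radii[1:2] > half_extent[1:2]))
    stop("spec error: body exceeds the grid in-plane", call. = FALSE)
  invisible(TRUE)
}

# world coordinates (mm) of every voxel, relative to grid center
phantom_coords <- function(spec) {
  ctr <- (spec$shape - 1) / 2 * spec$spacing
  list(x = (base_index_grids(spec$shape)$x - 1) * spec$spacing[1] - ctr[1],
       y = (base_index_grids(spec$shape)$y - 1) * spec$spacing[2] - ctr[2],
       z = (base_index_grids(spec$shape)$z - 1) * spec$spacing[3] - ctr[3])
}

#' Build the reference phantom volume and structure mask
#'
#' Deterministic for a given `spec` (the noise is seeded from
#' `spec$seed`).  With `noise_sd = 0` the volume takes exactly the four
#' nominal intensities.  The mask labels are
#' `1: body, 2: mandible, 3: parotid_L, 4: parotid_R` (structures override
#' the body label; the mask is noise-free).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [scalar_volume]) and `mask` (a
#'   [label_mask]).
#' @export
make_reference_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  sh <- spec$shape
  ints <- spec$intensities

  body <- (co$x / spec$body_radii[1])^2 + (co$y / spec$body_radii[2])^2 +
    (co$z / spec$body_radii[3])^2 <= 1

  m <- spec$mandible
  mx <- co$x - m$center_offset[1]
  my <- co$y - m$center_offset[2]
  mz <- co$z - m$center_offset[3]
  rad <- sqrt(mx^2 + my^2)
  # distance from the arc circle (in-plane) and along SI
  dist_ring <- sqrt((rad - m$arc_radius)^2 + mz^2)
  ang <- atan2(mx, -my) * 180 / pi  # 0 deg = anterior (-AP)
  mandible <- dist_ring <= m$tube_radius & abs(ang) <= m$half_angle & body

  p <- spec$parotid
  par_one <- function(sgn) {
    ((co$x - sgn * p$offset_lr) / p$radii[1])^2 +
      ((co$y - p$offset_ap) / p$radii[2])^2 +
      ((co$z - p$offset_si) / p$radii[3])^2 <= 1
  }
  parL <- par_one(-1) & body   # patient left = -LR here by convention
  parR <- par_one(+1) & body

  s <- spec$spine
  spine <- (co$x^2 + (co$y - s$offset_ap)^2) <= s$radius^2 & body

  vol <- rep(ints[["air"]], prod(sh))
  vol[body] <- ints[["body"]]
  if (spec$texture_amplitude > 0) {
    tex <- spec$texture_amplitude / 1.5 *
      (sin(2 * pi * co$x / 61) * cos(2 * pi * co$y / 47) +
         cos(2 * pi * co$x / 83 + 0.7) * sin(2 * pi * co$z / 71) +
         cos(2 * pi * co$y / 89 + 1.3) * cos(2 * pi * co$z / 53))
    vol[body] <- vol[body] + tex[body]
  }
  vol[spine] <- ints[["bone"]]
  vol[mandible] <- ints[["bone"]]
  vol[parL | parR] <- ints[["parotid"]]
  lab <- integer(prod(sh))
  lab[body | spine] <- 1L
  lab[mandible] <- 2L
  lab[parL] <- 3L
  lab[parR] <- 4L

  if (spec$noise_sd > 0) {
    with_preserved_rng(spec$seed, {
      vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
    })
  }
  dim(vol) <- sh
  dim(lab) <- sh
  list(volume = scalar_volume(vol, spec$spacing),
       mask = label_mask(lab, list(`1` = "body", `2` = "mandible",
                                   `3` = "parotid_L", `4` = "parotid_R"),
                         spec$spacing))
}

#' Smooth orthogonal latent deformation basis
#'
#' Builds `K` smooth, zero-boundary, mutually orthogonal (after
#' vectorization) deformation fields used as the known low-rank structure of
#' the synthetic population.  Each field starts as seeded Gaussian white
#' noise per component, is smoothed with a Gaussian of `smoothness_mm`,
#' windowed to the (feathered) body region and to zero on the grid
#' boundary, orthonormalized against the earlier fields (Gram-Schmidt on
#' the vectorized form), and finally scaled so its peak displacement
#' magnitude equals `magnitude_mm`.
#'
#' The body-support window (`body_support = TRUE`, the default) reflects
#' what the deformations stand for: anatomy deforms, the surrounding air
#' does not, and an intensity-driven registration can only ever observe
#' displacement where there is structure.
#'
#' @param spec a [phantom_spec()] providing the grid.
#' @param K number of basis fields.
#' @param magnitude_mm peak displacement magnitude after scaling.
#' @param smoothness_mm Gaussian smoothing sigma (mm).
#' @param seed integer seed.
#' @param body_support window the fields to the feathered body ellipsoid.
#' @return list of `K` [vector_field]s; attribute `unit_norm_fields` keeps
#'   the orthonormal (unscaled) vectorized basis as a matrix.
#' @export
make_latent_deformation_basis <- function(spec, K, magnitude_mm = 1,
                                          smoothness_mm = 24, seed = 1,
                                          body_support = TRUE) {
  stopifnot(K >= 1)
  sh <- spec$shape
  nv <- prod(sh)
  taper <- boundary_taper(sh)
  if (body_support) {
    co <- phantom_coords(spec)
    inside <- (co$x / spec$body_radii[1])^2 + (co$y / spec$body_radii[2])^2 +
      (co$z / spec$body_radii[3])^2 <= 1
    win <- array(as.numeric(inside), sh)
    win <- smooth_mm(win, 20, spec$spacing)
    taper <- taper * pmin(win / max(win), 1)
  }
  basis <- matrix(0, 3 * nv, K)
  with_preserved_rng(seed, {
    for (k in seq_len(K)) {
      comps <- lapply(1:3, function(i) {
        a <- array(rnorm(nv), sh)
        smooth_mm(a, smoothness_mm, spec$spacing) * taper
      })
      v <- c(as.vector(comps[[1]]), as.vector(comps[[2]]),
             as.vector(comps[[3]]))
      if (k > 1)
        v <- v - basis[, seq_len(k - 1), drop = FALSE] %*%
          crossprod(basis[, seq_len(k - 1), drop = FALSE], v)
      nrm <- sqrt(sum(v^2))
      if (nrm < 1e-12)
        stop("degenerate latent basis draw; use another seed", call. = FALSE)
      basis[, k] <- v / nrm
    }
  })
  grid <- list(shape = sh, spacing = spec$spacing, origin = c(0, 0, 0))
  fields <- lapply(seq_len(K), function(k) {
    f <- devectorize_field(basis[, k], grid)
    peak <- max(sqrt(f$dx^2 + f$dy^2 + f$dz^2))
    vector_field(f$dx * magnitude_mm / peak, f$dy * magnitude_mm / peak,
                 f$dz * magnitude_mm / peak, grid$spacing, grid$origin)
  })
  attr(fields, "unit_norm_fields") <- basis
  fields
}

# smooth per-axis taper, exactly zero on the one-voxel boundary shell
boundary_taper <- function(sh, ramp_voxels = 6) {
  ramp1 <- function(n) {
    w <- rep(1, n)
    r <- min(ramp_voxels, floor((n - 1) / 2))
    edge <- sin(pi / 2 * (seq_len(r) - 1) / r)^2  # 0 at the shell
    w[seq_len(r)] <- edge
    w[n + 1 - seq_len(r)] <- edge
    w[1] <- 0; w[n] <- 0
    w
  }
  wx <- ramp1(sh[1]); wy <- ramp1(sh[2]); wz <- ramp1(sh[3])
  outer(outer(wx, wy), wz)
}

#' Generate a synthetic population with known ground-truth deformations
#'
#' Emulates the training-data layout of a radiotherapy population: one
#' reference anatomy, `n_subjects` subject planning anatomies, and
#' `n_fractions` daily anatomies per subject, all derived from the reference
#' by smooth random deformations built on `K_inter` (between-subject) and
#' `K_intra` (between-fraction) latent modes with Gaussian weights (matching
#' the distributional assumption of the Mahalanobis-bounded sampler).
#'
#' The stored ground-truth fields (`true_inter`, `true_intra`) are the
#' low-rank latent combinations expressed in the direction a registration
#' pipeline estimates (subject-to-reference / daily-to-planning pull-back);
#' each anatomy is produced by warping with the iteratively inverted field
#' (`inter_applied`, `intra_applied`), so registering the volumes recovers
#' the low-rank truth directly.  Independent Gaussian noise is added to
#' every exposed volume; noise-free companions (`*_clean`) are stored
#' alongside for exact regeneration checks.
#'
#' A foldover guard redraws latent weights whose combined field peak would
#' exceed half the smallest body radius.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 2).
#' @param n_fractions daily volumes per subject (>= 1).
#' @param K_inter,K_intra latent mode counts.
#' @param weight_sd_inter,weight_sd_intra SD (mm) of the Gaussian latent
#'   weights; basis fields have unit peak magnitude, so these set the
#'   typical per-mode peak displacement.
#' @param smoothness_mm latent-field smoothness passed to
#'   [make_latent_deformation_basis()].
#' @param seed integer master seed.
#' @return an object of class `phantom_population`: list with `reference`
#'   (volume, clean volume, mask), `subjects` (each: `planning`,
#'   `planning_clean`, `true_inter`, `inter_applied`, `daily` list,
#'   `daily_clean` list, `true_intra` list, `intra_applied` list),
#'   `basis_inter`, `basis_intra`, `weights_inter`, `weights_intra`, and
#'   the generating `spec`.
#' @export
make_population <- function(spec = phantom_spec(texture_amplitude = 50),
                            n_subjects = 8,
                            n_fractions = 5, K_inter = 2, K_intra = 3,
                            weight_sd_inter = 5, weight_sd_intra = 8,
                            smoothness_mm = 32, seed = 42) {
  stopifnot(n_subjects >= 2, n_fractions >= 1)
  ref <- make_reference_phantom(spec)
  ref_clean0 <- phantom_spec_clean(spec)
  ref_clean <- make_reference_phantom(ref_clean0)$volume

  sub_seed <- function(k) as.integer((abs(seed) %% 100000L) * 1000L + k)
  basis_inter <- make_latent_deformation_basis(spec, K_inter,
                                               magnitude_mm = 1,
                                               smoothness_mm = smoothness_mm,
                                               seed = sub_seed(1L))
  basis_intra <- make_latent_deformation_basis(spec, K_intra,
                                               magnitude_mm = 1,
                                               smoothness_mm = smoothness_mm,
                                               seed = sub_seed(2L))
  # rescale each basis by one COMMON factor (typical peak = 1 mm) so all
  # latent modes carry equal variance per unit weight; per-mode peak scaling
  # would make the latent eigen-spectrum uneven and the generator's rank
  # structure harder to interpret
  basis_inter <- common_scale_basis(basis_inter)
  basis_intra <- common_scale_basis(basis_intra)
  fold_cap <- 0.5 * min(spec$body_radii)

  w_inter <- matrix(0, n_subjects, K_inter)
  w_intra <- array(0, c(n_subjects, n_fractions, K_intra))
  subjects <- vector("list", n_subjects)
  with_preserved_rng(seed, {
    for (i in seq_len(n_subjects)) {
      w_inter[i, ] <- draw_bounded_weights(K_inter, weight_sd_inter,
                                           basis_inter, fold_cap)
      # the low-rank combination is the truth in the REGISTRATION direction
      # (subject -> reference, what the learning pipeline estimates); the
      # anatomy is produced by warping with its iterative inverse
      d_inter <- combine_basis(basis_inter, w_inter[i, ])
      inv_inter <- invert_dvf(d_inter)
      plan_clean <- warp_volume(ref_clean, inv_inter)
      plan <- add_noise(plan_clean, spec$noise_sd)
      daily <- daily_clean <- true_intra <- intra_applied <-
        vector("list", n_fractions)
      for (j in seq_len(n_fractions)) {
        w_intra[i, j, ] <- draw_bounded_weights(K_intra, weight_sd_intra,
                                                basis_intra, fold_cap)
        # the latent combination is the subject's daily change expressed in
        # the common (reference) frame; the same anatomical change in the
        # subject's own geometry is that field carried along the subject's
        # inverse inter-patient mapping (anatomy-attached variation modes)
        d_intra <- combine_basis(basis_intra, w_intra[i, j, ])
        d_intra_subj <- transfer_dvf(d_intra, inv_inter)
        inv_intra <- invert_dvf(d_intra_subj)
        day_clean <- warp_volume(plan_clean, inv_intra)
        daily_clean[[j]] <- day_clean
        daily[[j]] <- add_noise(day_clean, spec$noise_sd)
        true_intra[[j]] <- d_intra
        intra_applied[[j]] <- inv_intra
      }
      subjects[[i]] <- list(planning = plan, planning_clean = plan_clean,
                            true_inter = d_inter,
                            inter_applied = inv_inter,
                            daily = daily,
                            daily_clean = daily_clean,
                            true_intra = true_intra,
                            intra_applied = intra_applied)
    }
  })
  structure(list(reference = list(volume = ref$volume,
                                  volume_clean = ref_clean,
                                  mask = ref$mask),
                 subjects = subjects,
                 basis_inter = basis_inter, basis_intra = basis_intra,
                 weights_inter = w_inter, weights_intra = w_intra,
                 spec = spec, seed = seed),
            class = "phantom_population")
}

phantom_spec_clean <- function(spec) {
  sp <- spec
  sp$noise_sd <- 0
  sp
}

# replace per-mode peak scaling with one shared factor: unit-norm fields
# scaled so the mean peak magnitude across modes is 1 mm
common_scale_basis <- function(basis) {
  U <- attr(basis, "unit_norm_fields")
  peaks <- vapply(seq_along(basis), function(k) {
    f <- basis[[k]]
    p <- max(sqrt(f$dx^2 + f$dy^2 + f$dz^2))
    # basis fields are peak-scaled to magnitude 1; recover unit-norm peak
    u <- devectorize_field(U[, k], list(shape = grid_shape(f),
                                        spacing = f$spacing,
                                        origin = f$origin))
    max(sqrt(u$dx^2 + u$dy^2 + u$dz^2))
  }, numeric(1))
  s <- 1 / mean(peaks)
  out <- lapply(seq_along(basis), function(k) {
    f <- basis[[k]]
    u <- devectorize_field(U[, k] * s, list(shape = grid_shape(f),
                                            spacing = f$spacing,
                                            origin = f$origin))
    u
  })
  attr(out, "unit_norm_fields") <- U
  attr(out, "common_scale") <- s
  out
}

combine_basis <- function(basis, w) {
  f <- basis[[1]]
  dx <- f$dx * w[1]; dy <- f$dy * w[1]; dz <- f$dz * w[1]
  for (k in seq_along(basis)[-1]) {
    dx <- dx + basis[[k]]$dx * w[k]
    dy <- dy + basis[[k]]$dy * w[k]
    dz <- dz + basis[[k]]$dz * w[k]
  }
  vector_field(dx, dy, dz, f$spacing, f$origin)
}

# folding check: peak magnitude cap plus a gradient bound.  The mapping
# x + d(x) stays invertible (and the fixed-point inversion contracts) when
# every partial derivative of every component is well below 1.
field_exceeds_fold <- function(field, cap_mm, grad_cap = 0.7) {
  peak <- max(sqrt(field$dx^2 + field$dy^2 + field$dz^2))
  if (peak > cap_mm) return(TRUE)
  for (comp in c("dx", "dy", "dz")) {
    g <- gradient3(field[[comp]], field$spacing)
    if (max(abs(g$gx), abs(g$gy), abs(g$gz)) > grad_cap) return(TRUE)
  }
  FALSE
}

guard_foldover <- function(field, cap_mm) {
  if (field_exceeds_fold(field, cap_mm))
    stop("spec error: generated deformation exceeds the foldover guard (",
         signif(cap_mm, 3), " mm peak / 0.7 gradient)", call. = FALSE)
  invisible(TRUE)
}

# Gaussian latent weights restricted to the non-folding set: a draw whose
# combined field peak exceeds the guard is redrawn (the anatomical
# counterpart of the Mahalanobis bound on sampled deformations); uses the
# caller's seeded RNG stream.
draw_bounded_weights <- function(K, sd_mm, basis, cap_mm, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    w <- rnorm(K, 0, sd_mm)
    if (!field_exceeds_fold(combine_basis(basis, w), cap_mm)) return(w)
  }
  stop("spec error: could not draw a deformation within the foldover guard (",
       signif(cap_mm, 3), " mm) in ", max_tries, " tries", call. = FALSE)
}

add_noise <- function(vol, noise_sd) {
  if (noise_sd <= 0) return(vol)
  # rely on the caller's (seeded) RNG stream
  scalar_volume(vol$data + array(rnorm(length(vol$data), 0, noise_sd),
                                 dim(vol$data)),
                vol$spacing, vol$origin)
}

#' @export
print.phantom_population <- function(x, ...) {
  cat(sprintf(paste0("<phantom_population> %d subjects x %d fractions on a ",
                     "%s grid\n"),
              length(x$subjects), length(x$subjects[[1]]$daily),
              paste(x$spec$shape, collapse = " x ")))
  cat(sprintf("  latent modes: %d inter, %d intra; noise SD %g HU; seed %d\n",
              length(x$basis_inter), length(x$basis_intra),
              x$spec$noise_sd, x$seed))
  invisible(x)
}
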