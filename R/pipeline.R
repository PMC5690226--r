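#' Build the inter-patient variation model from a population
#'
#' Workflow: every subject planning volume is rigidly aligned (integer
#' translation, cross-correlation) to the reference planning volume, all
#' volumes are cropped to the common space, each non-reference planning
#' volume is registered to the reference with [demons_register()], and an
#' active shape model is fitted to the resulting DVFs at retention level
#' `alpha` (default 90).  With `N` subjects this produces `N - 1` training
#' DVFs.
#'
#' @param population a `phantom_population` (or any list with the same
#'   layout: `reference$volume`, `subjects[[i]]$planning`).
#' @param reference_id which subject volume is the reference: 0 (default)
#'   uses the population's dedicated reference volume.  The reference choice
#'   is a configuration decision (clinically: the cohort-median patient),
#'   never automated.
#' @param alpha retention level, percent.
#' @param params a [demons_params()].  The model-building stages default to
#'   more iterations per level than `demons_params()` itself: training DVFs
#'   feed a covariance model, where incomplete convergence appears directly
#'   as spurious variance.
#' @param search_radius rigid-alignment search radius (voxels).
#' @param verbose log progress messages.
#' @return list with `model` (a `shape_model`), `ef_fields` (list of
#'   inter-patient DVFs on the reference grid), `reference` (the cropped
#'   reference volume), `translations`, and `provenance`.
#' @export
build_interpatient_model <- function(population, reference_id = 0,
                                     alpha = 90,
                                     params = demons_params(
                                       iterations_per_level = c(80, 50, 30)),
                                     search_radius = 2, verbose = FALSE) {
  subs <- population$subjects
  if (length(subs) < 3)
    stop("at least 3 subjects are required", call. = FALSE)
  ref_vol <- if (reference_id == 0) population$reference$volume
             else subs[[reference_id]]$planning
  moving_ids <- setdiff(seq_along(subs), reference_id)
  vols <- c(list(ref_vol), lapply(subs[moving_ids], `[[`, "planning"))
  trans <- c(list(c(0L, 0L, 0L)),
             lapply(vols[-1], function(v)
               rigid_align(v, ref_vol, search_radius = search_radius)))
  cropped <- crop_to_common_space(vols, trans)
  ref_c <- cropped[[1]]
  ef <- vector("list", length(moving_ids))
  names(ef) <- paste0("EF_", moving_ids)
  for (k in seq_along(moving_ids)) {
    if (verbose)
      message("registering planning volume of subject ", moving_ids[k],
              " to the reference")
    ef[[k]] <- demons_register(ref_c, cropped[[k + 1]], params)
    if (!is.null(attr(ef[[k]], "failed")))
      stop("registration failure on subject ", moving_ids[k], call. = FALSE)
  }
  model <- fit_shape_model(build_training_matrix(ef), alpha = alpha)
  list(model = model, ef_fields = ef, reference = ref_c,
       translations = setNames(trans, c("reference",
                                        paste0("subject_", moving_ids))),
       provenance = list(op = "build_interpatient_model", alpha = alpha,
                         reference_id = reference_id,
                         n_training_dvfs = length(ef),
                         params = unclass(params)))
}

#' Build the intra-patient variation model
#'
#' For each subject, registers every daily volume to that subject's planning
#' volume ([demons_register()]), yielding intra-patient DVFs in the
#' subject's planning space; transfers each to the reference space with
#' [transfer_dvf()] through the subject's inter-patient DVF (identity for
#' the reference subject); pools all transferred DVFs and fits a shape model
#' at `alpha` (default 95, higher than the inter-patient level because the
#' pooled intra-patient training set carries more distinct variation).
#'
#' @inheritParams build_interpatient_model
#' @param inter a result of [build_interpatient_model()] (provides the EF
#'   fields and the cropped reference grid).
#' @param include_reference_subject also register and pool the reference
#'   population subject's own daily volumes (transferred by the identity).
#' @return list with `model`, `if_fields` (pooled transferred DVFs),
#'   and `provenance`.
#' @export
build_intrapatient_model <- function(population, inter, alpha = 95,
                                     params = demons_params(
                                       iterations_per_level = c(80, 50, 30)),
                                     verbose = FALSE,
                                     include_reference_subject = TRUE) {
  subs <- population$subjects
  ef <- inter$ef_fields
  ref_grid_vol <- inter$reference
  pooled <- list()
  for (i in seq_along(subs)) {
    ef_name <- paste0("EF_", i)
    is_ref_subject <- !(ef_name %in% names(ef))
    if (is_ref_subject && !include_reference_subject) next
    if (!is_ref_subject && is.null(ef[[ef_name]]))
      stop("missing inter-patient DVF for subject ", i, call. = FALSE)
    plan <- conform_to(subs[[i]]$planning, ref_grid_vol)
    for (j in seq_along(subs[[i]]$daily)) {
      if (verbose)
        message("registering daily ", j, " of subject ", i,
                " to its planning volume")
      day <- conform_to(subs[[i]]$daily[[j]], ref_grid_vol)
      intra <- demons_register(plan, day, params)
      pooled[[length(pooled) + 1L]] <-
        if (is_ref_subject) intra else transfer_dvf(intra, ef[[ef_name]])
    }
  }
  model <- fit_shape_model(build_training_matrix(pooled), alpha = alpha)
  list(model = model, if_fields = pooled,
       provenance = list(op = "build_intrapatient_model", alpha = alpha,
                         n_training_dvfs = length(pooled),
                         params = unclass(params)))
}

# crop/pad-free conformation: volumes in these workflows share the reference
# grid after the inter-patient crop; re-crop if a volume is larger.
conform_to <- function(vol, target) {
  if (same_geometry(vol, target)) return(vol)
  sh <- grid_shape(target)
  shv <- grid_shape(vol)
  if (any(shv < sh))
    stop("geometry error: volume smaller than the reference space",
         call. = FALSE)
  scalar_volume(vol$data[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3]),
                         drop = FALSE],
                target$spacing, target$origin)
}

#' Generate an artificial planning/daily CT pair with known deformation
#'
#' Implements the generation workflow exactly in this order: sample `DE`
#' from the inter-patient model; invert it and warp the reference planning
#' volume by the inverse to obtain the artificial planning volume; for each
#' requested intra-patient `D_max`, sample `DT` from the intra-patient
#' model, transfer it through `DE` into the artificial planning space
#' (`DI <- transfer_dvf(DT, DE)`), invert `DI` and warp the artificial
#' planning volume by the inverse to obtain the artificial daily volume.
#' `DI` is the stored voxel-level ground-truth deformation for each daily
#' volume: registering daily to planning should recover it.  Masks, when
#' given, are propagated by the same inverted fields with nearest-neighbour
#' sampling.
#'
#' @param inter_model,intra_model `shape_model`s on one reference grid.
#' @param reference the reference [scalar_volume] (same grid).
#' @param D_max_inter Mahalanobis bound for the planning-level sample
#'   (default 3).
#' @param D_max_intra numeric vector of bounds, one artificial daily volume
#'   each (default `c(2, 3.5, 4.5)`).
#' @param seed integer seed; sub-seeds are derived deterministically.
#' @param mask optional [label_mask] on the reference grid.
#' @return list with `planning` (volume), `planning_mask` (or `NULL`),
#'   `DE`, and `dailies`: one entry per `D_max_intra` holding `volume`,
#'   `truth` (`DI`), `mask`, `D_max`, and inversion diagnostics.
#' @export
generate_artificial_pair <- function(inter_model, intra_model, reference,
                                     D_max_inter = 3,
                                     D_max_intra = c(2, 3.5, 4.5),
                                     seed = 1, mask = NULL) {
  stopifnot(inherits(inter_model, "shape_model"),
            inherits(intra_model, "shape_model"))
  if (!identical(inter_model$grid$shape, intra_model$grid$shape))
    stop("geometry mismatch: models must share the reference grid",
         call. = FALSE)
  sub_seed <- function(k) as.integer((abs(seed) %% 100000L) * 100L + k)
  de <- sample_deformation(inter_model, D_max_inter, sub_seed(1L))
  de_inv <- invert_dvf(de$field)
  planning <- warp_volume(reference, de_inv)
  planning_mask <- if (!is.null(mask)) warp_mask(mask, de_inv)
  notes <- list(de_converged = attr(de_inv, "converged"))
  dailies <- vector("list", length(D_max_intra))
  for (k in seq_along(D_max_intra)) {
    dt <- sample_deformation(intra_model, D_max_intra[k], sub_seed(1L + k))
    di <- transfer_dvf(dt$field, de$field)
    di_inv <- invert_dvf(di)
    dailies[[k]] <- list(
      volume = warp_volume(planning, di_inv),
      truth = di,
      mask = if (!is.null(planning_mask)) warp_mask(planning_mask, di_inv),
      D_max = D_max_intra[k],
      weights = dt$weights,
      di_converged = attr(di_inv, "converged"))
  }
  list(planning = planning, planning_mask = planning_mask, DE = de$field,
       DE_weights = de$weights, dailies = dailies,
       provenance = c(list(op = "generate_artificial_pair", seed = seed,
                           D_max_inter = D_max_inter,
                           D_max_intra = D_max_intra), notes))
}

#' Register artificial pairs and tabulate voxel-level validation statistics
#'
#' For every artificial daily volume, registers it to its artificial
#' planning volume with [demons_register()] (yielding `DN`), compares `DN`
#' with the stored ground truth `DI` via [error_map()], and reports, per
#' structure: the registration-error mean/SD/max and the ground-truth
#' deformation-magnitude mean/SD.
#'
#' @param pair a result of [generate_artificial_pair()] generated with a
#'   mask.
#' @param params a [demons_params()].
#' @param labels integer labels to evaluate (default: all structure labels
#'   present in the planning mask).
#' @param verbose log progress messages.
#' @return data frame with one row per (daily volume, structure):
#'   columns `D_max`, `structure`, `label`, `err_mean_mm`, `err_sd_mm`,
#'   `err_max_mm`, `def_mean_mm`, `def_sd_mm`, `n_voxels`.  The computed
#'   `DN` fields and error maps are attached as attributes.
#' @export
run_validation_experiment <- function(pair, params = demons_params(),
                                      labels = NULL, verbose = FALSE) {
  if (is.null(pair$planning_mask))
    stop("pair was generated without masks; structure statistics need them",
         call. = FALSE)
  pmask <- pair$planning_mask
  if (is.null(labels))
    labels <- as.integer(names(pmask$label_names))
  rows <- list()
  dn_fields <- list()
  emaps <- list()
  for (k in seq_along(pair$dailies)) {
    d <- pair$dailies[[k]]
    if (is.null(d$truth))
      stop("missing ground-truth field for daily volume ", k, call. = FALSE)
    if (verbose)
      message("registering daily volume ", k, " (D_max = ", d$D_max,
              ") to the artificial planning volume")
    dn <- demons_register(pair$planning, d$volume, params)
    em <- error_map(dn, d$truth)
    dn_fields[[k]] <- dn
    emaps[[k]] <- em
    for (lb in labels) {
      st <- structure_stats(em, pmask, lb)
      df <- mean_deformation_magnitude(d$truth, pmask, lb)
      rows[[length(rows) + 1L]] <- data.frame(
        D_max = d$D_max,
        structure = pmask$label_names[[as.character(lb)]],
        label = lb,
        err_mean_mm = st[["mean"]], err_sd_mm = st[["sd"]],
        err_max_mm = st[["max"]],
        def_mean_mm = df[["mean"]], def_sd_mm = df[["sd"]],
        n_voxels = st[["n"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dn_fields") <- dn_fields
  attr(out, "error_maps") <- emaps
  out
}
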