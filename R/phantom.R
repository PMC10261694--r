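#' Axial detector-sensitivity model
#'
#' Ring-type dedicated breast PET scanners collect fewer effective counts
#' near the axial ends of the field of view, so reconstructed noise is worst
#' at the first and last slices. The simulator models this with a relative
#' sensitivity profile along the slice axis: 1 at the axial centre, falling
#' monotonically to `edge_min` at either end.
#'
#' @param edge_min relative sensitivity in (0, 1] at the first/last slice.
#' @param profile `"cosine"` (half-sine arch, the default) or `"linear"`
#'   (triangular ramp).
#' @return An object of class `sensitivity_model`.
#' @export
sensitivity_model <- function(edge_min = 0.5,
                              profile = c("cosine", "linear")) {
  profile <- match.arg(profile)
  if (!is.numeric(edge_min) || length(edge_min) != 1L ||
      edge_min <= 0 || edge_min > 1)
    stop("`edge_min` must lie in (0, 1]", call. = FALSE)
  structure(list(edge_min = edge_min, profile = profile),
            class = "sensitivity_model")
}

#' Relative sensitivity at a slice
#'
#' @param z slice index (1-based), may be a vector.
#' @param n_slices number of slices in the volume.
#' @param model a [sensitivity_model()].
#' @return Relative sensitivity in `[edge_min, 1]`, symmetric about the
#'   axial centre and non-decreasing from either edge towards it.
#' @export
axial_sensitivity <- function(z, n_slices, model = sensitivity_model()) {
  stopifnot(inherits(model, "sensitivity_model"))
  if (any(z < 1 | z > n_slices | z != round(z)))
    stop("slice index out of range [1, n_slices]", call. = FALSE)
  if (n_slices == 1L) return(rep(1, length(z)))
  t <- (z - 1) / (n_slices - 1)
  shape <- switch(model$profile,
                  cosine = sin(pi * t),
                  linear = 1 - abs(2 * t - 1))
  model$edge_min + (1 - model$edge_min) * shape
}

#' Lesion description
#'
#' Lesions are FDG-avid uptake regions inserted into the phantom as uniform
#' plateaus on a sphere. `kind` follows the dbPET uptake-type classification
#' (focus, mass uptake, non-mass uptake); focus lesions are at most 10 mm in
#' diameter.
#'
#' @param kind one of `"focus"`, `"mass"`, `"non_mass"`.
#' @param center voxel coordinate `c(row, col, slice)` of the lesion centre.
#' @param diameter_mm lesion diameter in mm.
#' @param suv plateau SUV; must exceed the fibroglandular background.
#' @return An object of class `lesion`.
#' @export
lesion <- function(kind, center, diameter_mm, suv) {
  kind <- match.arg(kind, c("focus", "mass", "non_mass"))
  if (length(center) != 3L) stop("`center` must be (row, col, slice)",
                                 call. = FALSE)
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive", call. = FALSE)
  if (kind == "focus" && diameter_mm > 10)
    stop("focus lesions have diameter <= 10 mm", call. = FALSE)
  structure(list(kind = kind, center = as.integer(round(center)),
                 diameter_mm = diameter_mm, suv = suv),
            class = "lesion")
}

#' Breast phantom specification
#'
#' Parametric description of the synthetic breast used to stand in for
#' patient scans: a half-ellipsoid of tissue attached to the chest-wall edge
#' of the in-plane grid (row 1), filled with fat and fibroglandular
#' compartments, optional lesions, and the acquisition/noise model used to
#' simulate paired low-count (LC) and full-count (FC) scans.
#'
#' The defaults reproduce the acquisition geometry of a clinical dbPET
#' protocol: a 236 x 132 in-plane matrix with 0.78 mm isotropic voxels,
#' 3-minute LC and 7-minute FC durations, and a fibroglandular background of
#' SUV 1.18. `counts_per_suv_min` calibrates how many expected counts one SUV
#' contributes per minute of acquisition at full sensitivity; the default of
#' 15 puts the simulated FC gland coefficient of variation near 9%, the noise
#' level of a typical clinical reference image (a calibration default, not a
#' fit to any particular scan).
#'
#' @param n_slices number of axial slices.
#' @param slice_shape in-plane matrix size `c(rows, cols)`.
#' @param voxel_mm isotropic voxel size in mm.
#' @param suv_fat,suv_gland SUV of the fat and fibroglandular compartments;
#'   `suv_fat < suv_gland`.
#' @param gland_fraction proportion of breast volume assigned to
#'   fibroglandular tissue.
#' @param gland_texture_sigma smoothing length (voxels) of the random field
#'   whose thresholding produces the gland pattern; larger values give
#'   coarser, more connected gland regions.
#' @param lesions list of [lesion()] objects.
#' @param sensitivity a [sensitivity_model()].
#' @param duration_lc_min,duration_fc_min LC and FC acquisition durations in
#'   minutes (`duration_lc_min < duration_fc_min`).
#' @param counts_per_suv_min expected counts per voxel per SUV per minute at
#'   full sensitivity.
#' @param breast_semiaxes_rel half-ellipsoid semi-axes as fractions of the
#'   grid extent along (row, col, slice).
#' @param lesion_edge_blur_mm optional Gaussian blur of lesion edges in mm
#'   (0 = hard plateau).
#' @param noise_smooth_sigma optional in-plane Gaussian smoothing (voxels) of
#'   the simulated noise field, for emulating spatially correlated
#'   reconstruction noise; 0 (off) by default, and note that smoothing the
#'   noise field lowers its voxelwise variance.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 96,
                         slice_shape = c(236, 132),
                         voxel_mm = 0.78,
                         suv_fat = 0.30,
                         suv_gland = 1.18,
                         gland_fraction = 0.5,
                         gland_texture_sigma = 8,
                         lesions = list(),
                         sensitivity = sensitivity_model(),
                         duration_lc_min = 3,
                         duration_fc_min = 7,
                         counts_per_suv_min = 15,
                         breast_semiaxes_rel = c(0.9, 0.45, 0.75),
                         lesion_edge_blur_mm = 0,
                         noise_smooth_sigma = 0) {
  if (any(c(suv_fat, suv_gland) < 0)) stop("SUVs must be >= 0", call. = FALSE)
  if (suv_fat >= suv_gland)
    stop("`suv_fat` must be below `suv_gland`", call. = FALSE)
  if (duration_lc_min >= duration_fc_min)
    stop("`duration_lc_min` must be below `duration_fc_min`", call. = FALSE)
  if (gland_fraction < 0 || gland_fraction > 1)
    stop("`gland_fraction` must lie in [0, 1]", call. = FALSE)
  if (counts_per_suv_min <= 0)
    stop("`counts_per_suv_min` must be positive", call. = FALSE)
  stopifnot(inherits(sensitivity, "sensitivity_model"),
            length(slice_shape) == 2L, n_slices >= 1,
            length(breast_semiaxes_rel) == 3L)
  for (l in lesions) stopifnot(inherits(l, "lesion"))
  structure(
    list(n_slices = as.integer(n_slices),
         slice_shape = as.integer(slice_shape), voxel_mm = voxel_mm,
         suv_fat = suv_fat, suv_gland = suv_gland,
         gland_fraction = gland_fraction,
         gland_texture_sigma = gland_texture_sigma,
         lesions = lesions, sensitivity = sensitivity,
         duration_lc_min = duration_lc_min,
         duration_fc_min = duration_fc_min,
         counts_per_suv_min = counts_per_suv_min,
         breast_semiaxes_rel = breast_semiaxes_rel,
         lesion_edge_blur_mm = lesion_edge_blur_mm,
         noise_smooth_sigma = noise_smooth_sigma),
    class = "phantom_spec")
}

# Logical breast mask: half-ellipsoid attached to the chest-wall (row 1)
# in-plane edge, centred in column and slice.
breast_mask <- function(spec) {
  R <- spec$slice_shape[1]; C <- spec$slice_shape[2]; Z <- spec$n_slices
  ax <- spec$breast_semiaxes_rel
  a <- ax[1] * R; b <- ax[2] * C; cz <- ax[3] * Z
  if (a <= 0 || b <= 0 || cz <= 0)
    return(array(FALSE, dim = c(R, C, Z)))
  r <- (seq_len(R) - 1) / a
  cc <- (seq_len(C) - (C + 1) / 2) / b
  zz <- (seq_len(Z) - (Z + 1) / 2) / cz
  d2 <- outer(outer(r^2, cc^2, `+`), zz^2, `+`)
  array(d2 <= 1, dim = c(R, C, Z))
}

# Voxel offsets (n x 3) whose centres lie within radius_mm of a sphere centre.
sphere_offsets <- function(radius_mm, voxel_mm) {
  rv <- radius_mm / voxel_mm
  m <- floor(rv)
  g <- expand.grid(dr = -m:m, dc = -m:m, dz = -m:m)
  g <- g[g$dr^2 + g$dc^2 + g$dz^2 <= rv^2, , drop = FALSE]
  as.matrix(g)
}

#' Generate a noise-free breast activity map
#'
#' Builds the ground-truth SUV volume for one phantom: fat/fibroglandular
#' tissue inside the breast mask (the gland pattern is a seeded smooth random
#' field thresholded at `gland_fraction`), lesion plateaus, and zero (air)
#' outside the breast.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same `(spec, seed)` pair always produces an
#'   identical volume.
#' @return An [activity_volume()] whose `masks` element holds the logical
#'   `breast`, `gland` and `lesion` masks.
#' @export
generate_activity_map <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- c(spec$slice_shape, spec$n_slices)
  mask <- breast_mask(spec)
  values <- array(0, dim = dims)
  gland <- array(FALSE, dim = dims)

  if (any(mask)) {
    field <- with_seed(seed, array(rnorm(prod(dims)), dim = dims))
    field <- gaussian_smooth_array(
      field, sigma_vox = c(rep(spec$gland_texture_sigma, 2),
                           spec$gland_texture_sigma / 2))
    if (spec$gland_fraction >= 1) {
      gland <- mask
    } else if (spec$gland_fraction > 0) {
      thr <- quantile(field[mask], probs = 1 - spec$gland_fraction,
                      names = FALSE)
      gland <- mask & (field >= thr)
    }
    values[mask] <- spec$suv_fat
    values[gland] <- spec$suv_gland
  }

  lesion_mask <- array(FALSE, dim = dims)
  for (les in spec$lesions) {
    off <- sphere_offsets(les$diameter_mm / 2, spec$voxel_mm)
    vox <- cbind(off[, 1] + les$center[1], off[, 2] + les$center[2],
                 off[, 3] + les$center[3])
    inside_grid <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
      vox[, 2] >= 1 & vox[, 2] <= dims[2] &
      vox[, 3] >= 1 & vox[, 3] <= dims[3]
    if (!all(inside_grid) || !all(mask[vox[inside_grid, , drop = FALSE]]))
      stop(sprintf(
        "lesion at (%d, %d, %d) with diameter %.1f mm extends outside the breast mask",
        les$center[1], les$center[2], les$center[3], les$diameter_mm),
        call. = FALSE)
    if (spec$lesion_edge_blur_mm > 0) {
      delta <- array(0, dim = dims)
      delta[vox] <- les$suv - values[vox]
      delta <- gaussian_smooth_array(
        delta, sigma_vox = rep(spec$lesion_edge_blur_mm / spec$voxel_mm, 3))
      values <- values + delta
    } else {
      values[vox] <- les$suv
    }
    lesion_mask[vox] <- TRUE
  }

  activity_volume(values, spacing = spec$voxel_mm,
                  masks = list(breast = mask, gland = gland & !lesion_mask,
                               lesion = lesion_mask))
}

#' Simulate one acquisition of an activity map
#'
#' Per voxel, the expected number of detected counts is
#' `activity * duration_min * sensitivity(z) * counts_per_suv_min`; a Poisson
#' draw with that mean is rescaled back to SUV by the same factor. The
#' simulated volume is therefore unbiased for the activity and its voxel
#' variance is `activity / (duration * sensitivity(z) * counts_per_suv_min)`:
#' noise falls with the square root of acquisition time and rises towards the
#' axial field-of-view edge.
#'
#' @param activity an [activity_volume()].
#' @param duration_min acquisition duration in minutes (> 0).
#' @param spec the [phantom_spec()] providing the sensitivity model and count
#'   calibration.
#' @param seed integer seed; identical inputs give identical output.
#' @param meta provenance tag for the returned volume.
#' @return A [pet_volume()].
#' @export
simulate_scan <- function(activity, duration_min, spec, seed, meta = "sim") {
  stopifnot(inherits(activity, "activity_volume"),
            inherits(spec, "phantom_spec"))
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("`duration_min` must be positive", call. = FALSE)
  dims <- dim(activity$values)
  sens <- axial_sensitivity(seq_len(dims[3]), dims[3], spec$sensitivity)
  f <- rep(sens * duration_min * spec$counts_per_suv_min,
           each = dims[1] * dims[2])
  lam <- as.vector(activity$values) * f
  draws <- with_seed(seed, rpois(length(lam), lam))
  sim <- array(draws / f, dim = dims)
  if (spec$noise_smooth_sigma > 0) {
    noise <- sim - activity$values
    noise <- gaussian_smooth_array(
      noise, sigma_vox = c(rep(spec$noise_smooth_sigma, 2), 0))
    sim <- activity$values + noise
  }
  pet_volume(sim, spacing = activity$spacing,
             duration_min = duration_min, meta = meta)
}

#' Sample a realistic lesion set for a phantom
#'
#' Draws one or two lesions per phantom from the uptake-type mixture observed
#' in clinical dbPET series (about 27% focus, 73% mass uptake), with plateau
#' SUVs around 2.84 +/- 0.85 for focus and 12.61 +/- 8.05 for mass lesions
#' (truncated above the gland background). Centres are rejection-sampled so
#' that the lesion sphere lies inside the breast and a 10 mm SUVpeak ROI
#' around it stays inside the image grid.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param n number of lesions; default samples 1 or 2.
#' @return A list of [lesion()] objects (possibly shorter than `n` when the
#'   geometry cannot accommodate all lesions).
#' @export
sample_lesions <- function(spec, seed, n = NULL) {
  mask <- breast_mask(spec)
  dims <- dim(mask)
  with_seed(seed, {
    if (is.null(n)) n <- 1L + stats::rbinom(1L, 1L, 0.7)
    out <- list()
    cand <- which(mask, arr.ind = TRUE)
    if (nrow(cand) == 0L) return(out)
    for (i in seq_len(n)) {
      kind <- sample(c("focus", "mass"), 1L, prob = c(6, 16))
      if (kind == "focus") {
        diam <- stats::runif(1, 4, 9)
        suv <- max(spec$suv_gland + 0.3, rnorm(1, 2.84, 0.85))
      } else {
        diam <- stats::runif(1, 10, 16)
        suv <- max(spec$suv_gland + 1.0, rnorm(1, 12.61, 8.05))
      }
      off <- sphere_offsets(diam / 2, spec$voxel_mm)
      margin_px <- ceiling(5 / spec$voxel_mm) + 2L  # 10 mm peak ROI + slack
      placed <- FALSE
      for (try in seq_len(300L)) {
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        vox <- sweep(off, 2L, ctr, `+`)
        if (any(vox[, 1] < 1 + margin_px | vox[, 1] > dims[1] - margin_px |
                vox[, 2] < 1 + margin_px | vox[, 2] > dims[2] - margin_px |
                vox[, 3] < 2 | vox[, 3] > dims[3] - 1)) next
        if (!all(mask[vox])) next
        too_close <- FALSE
        for (prev in out) {
          gap <- sqrt(sum((ctr - prev$center)^2)) * spec$voxel_mm
          if (gap < (diam + prev$diameter_mm) / 2 + 4 * spec$voxel_mm)
            too_close <- TRUE
        }
        if (too_close) next
        out[[length(out) + 1L]] <- lesion(kind, ctr, diam, suv)
        placed <- TRUE
        break
      }
      if (!placed) next
    }
    out
  })
}

#' Simulate a paired low-count / full-count dataset
#'
#' For each phantom, draws a lesion set (unless the spec fixes one), builds
#' the noise-free activity map, and simulates one LC and one FC acquisition
#' from it with independent noise.
#'
#' @param spec a [phantom_spec()]; its `duration_lc_min` / `duration_fc_min`
#'   set the two acquisition durations.
#' @param n_phantoms number of phantoms (>= 1).
#' @param seed integer seed; the whole dataset is reproducible from
#'   `(spec, n_phantoms, seed)`.
#' @param random_lesions if `TRUE` (default) each phantom gets its own lesion
#'   set from [sample_lesions()]; if `FALSE`, `spec$lesions` is used as-is
#'   for every phantom.
#' @return A list with one element per phantom, each a list with components
#'   `lc`, `fc` ([pet_volume()]s), `activity` ([activity_volume()]) and
#'   `lesions`.
#' @export
make_paired_dataset <- function(spec, n_phantoms, seed,
                                random_lesions = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_phantoms < 1) stop("`n_phantoms` must be >= 1", call. = FALSE)
  seeds <- matrix(derive_seeds(seed, 4L * n_phantoms), nrow = 4L)
  lapply(seq_len(n_phantoms), function(i) {
    spec_i <- spec
    if (random_lesions)
      spec_i$lesions <- sample_lesions(spec, seeds[1L, i])
    act <- generate_activity_map(spec_i, seeds[2L, i])
    lc <- simulate_scan(act, spec$duration_lc_min, spec, seeds[3L, i],
                        meta = "LC")
    fc <- simulate_scan(act, spec$duration_fc_min, spec, seeds[4L, i],
                        meta = "FC")
    list(lc = lc, fc = fc, activity = act, lesions = spec_i$lesions)
  })
}
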