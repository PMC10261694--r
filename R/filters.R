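#' Gaussian post-filter parameters
#'
#' @param fwhm_mm full width at half maximum of the Gaussian kernel in mm
#'   (>= 0; 0 means no smoothing). The 1.17 mm default matches the
#'   post-smoothing used to create clinical dbPET reference images.
#' @param axes `"3d"` applies the kernel along all three axes (the default,
#'   matching common PET post-smoothing practice); `"2d"` smooths in-plane
#'   only.
#' @return An object of class `gaussian_params`.
#' @export
gaussian_params <- function(fwhm_mm = 1.17, axes = c("3d", "2d")) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  structure(list(fwhm_mm = fwhm_mm, axes = match.arg(axes)),
            class = "gaussian_params")
}

#' Convert a FWHM in mm to a Gaussian sigma in voxel units
#'
#' `sigma = fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_mm)`.
#'
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @param voxel_mm voxel size in mm (> 0).
#' @return Standard deviation of the kernel in voxels.
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (voxel_mm <= 0) stop("`voxel_mm` must be > 0", call. = FALSE)
  fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_mm)
}

# Reflect (symmetric, edge-duplicating) out-of-range 1-based indices.
reflect_idx <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# 1-d convolution of a 3-d array along one axis with a unit-sum kernel and
# symmetric boundary handling.
conv1d_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dim(m) <- c(n, prod(d[perm][-1]))
  pad <- m[reflect_idx(seq.int(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[j:(j + n - 1L), , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# Smooth a 3-d array with per-axis Gaussian sigmas (in voxels).
gaussian_smooth_array <- function(a, sigma_vox) {
  for (axis in 1:3)
    if (sigma_vox[axis] > 0)
      a <- conv1d_axis(a, gaussian_kernel_1d(sigma_vox[axis]), axis)
  a
}

#' Apply a Gaussian post-filter to a PET volume
#'
#' Separable Gaussian convolution with the sigma implied by the FWHM, the
#' same kernel along every smoothed axis (isotropic voxels), unit-sum kernel
#' and reflective boundaries. Constant volumes are preserved exactly and a
#' zero FWHM returns the input values unchanged.
#'
#' @param vol a [pet_volume()].
#' @param params a [gaussian_params()].
#' @return A [pet_volume()] tagged with `"+Gaussian"` provenance.
#' @export
gaussian_post_filter <- function(vol, params = gaussian_params()) {
  stopifnot(inherits(vol, "pet_volume"), inherits(params, "gaussian_params"))
  sigma <- fwhm_to_sigma(params$fwhm_mm, vol$spacing)
  sig3 <- if (params$axes == "3d") rep(sigma, 3) else c(sigma, sigma, 0)
  out <- if (sigma > 0) gaussian_smooth_array(vol$values, sig3) else
    vol$values
  pet_volume(out, spacing = vol$spacing, duration_min = vol$duration_min,
             meta = paste0(vol$meta, "+Gaussian"))
}

#' Pooled background standard deviation
#'
#' Pools the pixel values of all supplied ROIs into one sample and returns
#' its standard deviation (n - 1 denominator). Used to set the NLM filtering
#' strength from the background fibroglandular tissue of low-count images.
#'
#' @param vol a [pet_volume()].
#' @param rois a non-empty list of ROIs (see [roi_circle()], [roi_rect()]).
#' @return A single SUV-valued standard deviation.
#' @export
estimate_background_sigma <- function(vol, rois) {
  if (length(rois) == 0L) stop("at least one ROI is required", call. = FALSE)
  vals <- unlist(lapply(rois, function(r) roi_values(vol, r)))
  if (length(vals) < 2L)
    stop("ROIs must contain at least two pixels in total", call. = FALSE)
  sd(vals)
}

#' Non-local means filter parameters
#'
#' @param patch odd patch side length in pixels (default 3, i.e. 3x3).
#' @param search odd search-window side length in pixels (default 5, 5x5).
#' @param h filtering strength in SUV; weights are
#'   `exp(-D^2 / h^2)` where `D^2` is the patch-size-normalised squared
#'   Euclidean distance between patches. Typically set to the background
#'   standard deviation of the image being filtered
#'   (see [estimate_background_sigma()]); `NULL` defers the choice to the
#'   pipeline.
#' @param self_weight_rule `"self-zero"` (default) lets the centre pixel keep
#'   the weight of its zero self-distance; `"max-neighbor"` replaces it with
#'   the largest weight among the other window pixels (the Buades
#'   convention).
#' @param patch_weighting `"uniform"` (default) weights all patch pixels
#'   equally (1/patch^2); `"gaussian"` uses a normalised Gaussian profile
#'   over the patch (sigma = patch radius / 2).
#' @return An object of class `nlm_params`.
#' @export
nlm_params <- function(patch = 3, search = 5, h = NULL,
                       self_weight_rule = c("self-zero", "max-neighbor"),
                       patch_weighting = c("uniform", "gaussian")) {
  if (patch %% 2 == 0 || search %% 2 == 0)
    stop("`patch` and `search` must be odd", call. = FALSE)
  if (patch > search) stop("`patch` must not exceed `search`", call. = FALSE)
  if (!is.null(h) && (!is.numeric(h) || h <= 0))
    stop("`h` must be positive", call. = FALSE)
  structure(list(patch = as.integer(patch), search = as.integer(search),
                 h = h, self_weight_rule = match.arg(self_weight_rule),
                 patch_weighting = match.arg(patch_weighting)),
            class = "nlm_params")
}

nlm_patch_weights <- function(params) {
  pr <- (params$patch - 1L) / 2L
  if (params$patch_weighting == "uniform" || pr == 0L)
    return(rep(1 / params$patch^2, params$patch^2))
  k1 <- dnorm(seq.int(-pr, pr), sd = max(pr / 2, 0.5))
  w <- outer(k1, k1)
  as.vector(w / sum(w))
}

#' Apply a slice-wise non-local means filter
#'
#' For each pixel of each axial slice, computes a weighted average of the
#' pixel values in its search window, with weights `exp(-D^2 / h^2)` from the
#' patch-distance `D^2` (normalised by the number of patch pixels), weights
#' normalised to sum to one, and reflective padding at slice borders. Output
#' pixels are convex combinations of their search window, so constant slices
#' are fixed points and values never leave the window's range.
#'
#' @param vol a [pet_volume()].
#' @param params an [nlm_params()] with a concrete `h`.
#' @return A [pet_volume()] tagged with `"+NLM"` provenance.
#' @export
nlm_filter <- function(vol, params) {
  stopifnot(inherits(vol, "pet_volume"), inherits(params, "nlm_params"))
  if (is.null(params$h)) stop("`params$h` must be set", call. = FALSE)
  pw <- nlm_patch_weights(params)
  rule <- if (params$self_weight_rule == "self-zero") 0L else 1L
  out <- vol$values
  for (z in seq_len(dim(out)[3]))
    out[, , z] <- .nlm_slice(vol$values[, , z], params$patch, params$search,
                             params$h, pw, rule)
  pet_volume(out, spacing = vol$spacing, duration_min = vol$duration_min,
             meta = paste0(vol$meta, "+NLM"))
}
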