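#' PET volume container
#'
#' A `pet_volume` holds a 3-d grid of standardized uptake values (SUV)
#' indexed `[row, col, slice]`, where the slice index runs along the axial
#' direction of the scanner (the direction along which detector sensitivity,
#' and therefore noise, varies). `spacing` is the isotropic voxel size in mm,
#' `duration_min` the emission time the volume represents, and `meta` a free
#' provenance tag such as `"LC"`, `"FC"`, `"LC+DL"` or `"FC+Gaussian"`.
#'
#' @param values 3-d numeric array of SUV, finite everywhere.
#' @param spacing isotropic voxel size in mm.
#' @param duration_min acquisition duration in minutes (may be `NA` for
#'   volumes that do not correspond to an acquisition, e.g. filtered copies
#'   inherit the duration of their source).
#' @param meta character provenance tag.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing, duration_min = NA_real_, meta = "") {
  values <- as_vol_array(values)
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive voxel size in mm", call. = FALSE)
  structure(
    list(values = values, spacing = spacing,
         duration_min = duration_min, meta = as.character(meta)),
    class = "pet_volume")
}

#' Noise-free activity volume
#'
#' The ground-truth SUV map a phantom simulation is built from: zero outside
#' the breast, tissue SUV levels inside. `masks`, when present, carries the
#' logical breast / gland / lesion masks the generator used, which downstream
#' ROI placement reuses.
#'
#' @param values 3-d numeric array of noise-free SUV (non-negative).
#' @param spacing isotropic voxel size in mm.
#' @param masks optional named list of logical arrays (`breast`, `gland`,
#'   `lesion`) with the same dimensions as `values`.
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(values, spacing, masks = NULL) {
  values <- as_vol_array(values)
  if (any(values < 0)) stop("activity must be non-negative", call. = FALSE)
  structure(list(values = values, spacing = spacing, masks = masks),
            class = "activity_volume")
}

as_vol_array <- function(values) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array [row, col, slice]", call. = FALSE)
  storage.mode(values) <- "double"
  values
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume %s> %d x %d x %d voxels, %.2f mm, %s min\n",
              x$meta, d[1], d[2], d[3], x$spacing,
              format(x$duration_min)))
  cat(sprintf("  SUV range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<activity_volume> %d x %d x %d voxels, %.2f mm\n",
              d[1], d[2], d[3], x$spacing))
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as `.nii.gz` with the voxel spacing in the header.
#' Acquisition duration and the provenance tag do not fit the NIfTI header,
#' so they travel in a JSON sidecar (`<file>.json`) written next to the
#' image; `read_volume()` picks the sidecar up when present.
#'
#' @param vol a [pet_volume()].
#' @param file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `file` invisibly; `read_volume()` returns
#'   a [pet_volume()].
#' @export
write_volume <- function(vol, file) {
  stopifnot(inherits(vol, "pet_volume"))
  img <- RNifti::asNifti(vol$values,
                         pixdim = rep(vol$spacing, 3L))
  RNifti::writeNifti(img, file)
  side <- sidecar_path(file)
  jsonlite::write_json(
    list(duration_min = vol$duration_min, meta = vol$meta,
         spacing = vol$spacing),
    side, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_volume
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  spacing <- RNifti::pixdim(img)[1]
  vals <- array(as.numeric(img), dim = dim(img))
  duration <- NA_real_
  meta <- ""
  side <- sidecar_path(file)
  if (file.exists(side)) {
    info <- jsonlite::read_json(side, simplifyVector = TRUE)
    duration <- info$duration_min %||% NA_real_
    meta <- info$meta %||% ""
    if (!is.null(info$spacing)) spacing <- info$spacing
  }
  pet_volume(vals, spacing = spacing, duration_min = duration, meta = meta)
}

sidecar_path <- function(file) {
  sub("\\.nii(\\.gz)?$", ".json", file)
}
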