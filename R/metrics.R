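#' Regions of interest
#'
#' ROIs are 2-d regions bound to a single axial slice. A circular ROI is
#' defined by its centre pixel and a physical diameter; a pixel belongs to the
#' circle when its centre lies within the radius (the pixelisation convention
#' used throughout the package). A rectangular ROI is defined by its origin
#' pixel (top-left) and a height/width in pixels.
#'
#' @param slice 1-based slice index.
#' @param center_rc circle centre `c(row, col)` in pixels.
#' @param diameter_mm circle diameter in mm.
#' @param voxel_mm pixel size in mm.
#' @param origin_rc rectangle origin `c(row, col)` (top-left pixel).
#' @param height_px,width_px rectangle extent in pixels.
#' @return An object of class `roi`.
#' @export
roi_circle <- function(slice, center_rc, diameter_mm, voxel_mm) {
  off <- circle_offsets(diameter_mm, voxel_mm)
  px <- cbind(off[, 1] + center_rc[1], off[, 2] + center_rc[2])
  structure(list(slice = as.integer(slice), shape = "circle",
                 center_rc = center_rc, diameter_mm = diameter_mm,
                 voxel_mm = voxel_mm, pixels = px),
            class = "roi")
}

#' @rdname roi_circle
#' @export
roi_rect <- function(slice, origin_rc, height_px, width_px) {
  px <- as.matrix(expand.grid(
    row = origin_rc[1] + seq_len(height_px) - 1L,
    col = origin_rc[2] + seq_len(width_px) - 1L))
  structure(list(slice = as.integer(slice), shape = "rectangle",
                 origin_rc = origin_rc, height_px = height_px,
                 width_px = width_px, pixels = px),
            class = "roi")
}

# 2-d pixel offsets whose centres lie within diameter/2 of the origin.
circle_offsets <- function(diameter_mm, voxel_mm) {
  rv <- (diameter_mm / 2) / voxel_mm
  m <- floor(rv)
  g <- expand.grid(dr = -m:m, dc = -m:m)
  as.matrix(g[g$dr^2 + g$dc^2 <= rv^2, , drop = FALSE])
}

#' Extract the pixel values of an ROI from a volume
#'
#' @param vol a [pet_volume()].
#' @param roi an ROI from [roi_circle()] or [roi_rect()].
#' @return Numeric vector of the member pixel values.
#' @export
roi_values <- function(vol, roi) {
  stopifnot(inherits(vol, "pet_volume"), inherits(roi, "roi"))
  d <- dim(vol$values)
  px <- roi$pixels
  if (roi$slice < 1 || roi$slice > d[3] ||
      any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2]))
    stop("ROI extends outside the image grid", call. = FALSE)
  vol$values[cbind(px, roi$slice)]
}

#' SUVmean, SD and coefficient of variation of an ROI
#'
#' `suv_mean` is the arithmetic mean, `sd` the sample standard deviation
#' (n - 1), and `cv = sd / suv_mean * 100` (%). When `suv_mean` is zero the
#' CV is undefined and reported as `NA`.
#'
#' @param vol a [pet_volume()].
#' @param roi an ROI with at least two member pixels.
#' @return A list with elements `suv_mean`, `sd`, `cv` and `n_pixels`.
#' @export
roi_stats <- function(vol, roi) {
  vals <- roi_values(vol, roi)
  if (length(vals) < 2L) stop("ROI must contain >= 2 pixels", call. = FALSE)
  m <- mean(vals)
  s <- sd(vals)
  structure(list(suv_mean = m, sd = s,
                 cv = if (m > 0) s / m * 100 else NA_real_,
                 n_pixels = length(vals)),
            class = "roi_stats")
}

# TRUE where the 2-d logical matrix `ok` is TRUE at (r + dr, c + dc) for
# every offset; FALSE wherever a shifted position leaves the grid.
all_offsets_ok <- function(ok, offsets) {
  d <- dim(ok)
  out <- matrix(TRUE, d[1], d[2])
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets[i, 1]; dc <- offsets[i, 2]
    sh <- matrix(FALSE, d[1], d[2])
    r_src <- max(1, 1 + dr):min(d[1], d[1] + dr)
    c_src <- max(1, 1 + dc):min(d[2], d[2] + dc)
    sh[r_src - dr, c_src - dc] <- ok[r_src, c_src]
    out <- out & sh
  }
  out
}

# Seeded selection of n slices, pairwise >= gap apart, from the eligible set.
select_gapped_slices <- function(eligible, n, gap, n_try = 500L) {
  if (length(eligible) >= n) {
    for (i in seq_len(n_try)) {
      perm <- sample(eligible)
      keep <- integer(0)
      for (z in perm)
        if (all(abs(z - keep) >= gap)) keep <- c(keep, z)
      if (length(keep) >= n) return(sort(keep[seq_len(n)]))
    }
  }
  # deterministic feasibility check: greedy on the sorted set is maximal
  srt <- sort(eligible)
  keep <- integer(0)
  for (z in srt) if (all(abs(z - keep) >= gap)) keep <- c(keep, z)
  if (length(keep) >= n) return(keep[seq_len(n)])
  stop(sprintf(
    "cannot place %d ROIs on slices >= %d apart: only %d eligible slices satisfy the gap constraint",
    n, gap, length(keep)), call. = FALSE)
}

#' Automated background ROI placement
#'
#' Places `n` circular ROIs of `diameter_mm` on background fibroglandular
#' tissue: each ROI lies fully inside the gland mask (and outside any lesion
#' mask), on `n` distinct slices that are pairwise at least `min_slice_gap`
#' slices apart. Placement is randomised but fully determined by `seed`.
#'
#' @param vol a [pet_volume()].
#' @param gland_mask logical array marking background fibroglandular tissue.
#' @param n number of ROIs (default 5).
#' @param diameter_mm ROI diameter (default 8 mm).
#' @param min_slice_gap minimum slice-index distance between ROIs (default 5).
#' @param seed integer seed.
#' @param lesion_mask optional logical array of lesion voxels to avoid.
#' @return A list of `n` circular ROIs.
#' @export
place_background_rois <- function(vol, gland_mask, n = 5, diameter_mm = 8,
                                  min_slice_gap = 5, seed,
                                  lesion_mask = NULL) {
  stopifnot(inherits(vol, "pet_volume"))
  d <- dim(vol$values)
  stopifnot(identical(dim(gland_mask), d))
  off <- circle_offsets(diameter_mm, vol$spacing)
  with_seed(seed, {
    elig <- vector("list", d[3])
    for (z in seq_len(d[3])) {
      ok <- gland_mask[, , z]
      if (!is.null(lesion_mask)) ok <- ok & !lesion_mask[, , z]
      if (!any(ok)) { elig[[z]] <- matrix(integer(0), 0, 2); next }
      cen <- all_offsets_ok(ok, off)
      elig[[z]] <- which(cen, arr.ind = TRUE)
    }
    slices_ok <- which(vapply(elig, nrow, 1L) > 0L)
    if (length(slices_ok) == 0L)
      stop("no slice admits a fully interior background ROI", call. = FALSE)
    slices <- select_gapped_slices(slices_ok, n, min_slice_gap)
    lapply(slices, function(z) {
      ctr <- elig[[z]][sample.int(nrow(elig[[z]]), 1L), ]
      roi_circle(z, ctr, diameter_mm, vol$spacing)
    })
  })
}

#' Automated field-of-view-edge ROI placement
#'
#' Places `n` rectangular ROIs (default 10 x 30 pixels) whose near edge sits
#' exactly `edge_offset` pixels from the chest-wall (row 1) border of the
#' in-plane field of view, confined to tissue, on slices drawn from the first
#' and last `edge_band` slices of the volume — the axial region where
#' detector sensitivity, and therefore noise, is worst. Chosen slices are
#' pairwise at least `min_slice_gap` apart; placement is seed-deterministic.
#'
#' @param vol a [pet_volume()].
#' @param tissue_mask logical array of tissue (breast) voxels.
#' @param n number of ROIs (default 5).
#' @param rect_px rectangle `c(height, width)` in pixels (default 10 x 30).
#' @param edge_offset gap in pixels between the FOV border and the near edge
#'   of the rectangle (default 5).
#' @param min_slice_gap minimum slice-index distance between ROIs (default 5).
#' @param edge_band how many slices at each axial end are considered "edge"
#'   slices (default 12).
#' @param seed integer seed.
#' @return A list of `n` rectangular ROIs.
#' @export
place_edge_rois <- function(vol, tissue_mask, n = 5, rect_px = c(10, 30),
                            edge_offset = 5, min_slice_gap = 5,
                            edge_band = 12, seed) {
  stopifnot(inherits(vol, "pet_volume"))
  d <- dim(vol$values)
  stopifnot(identical(dim(tissue_mask), d))
  rows <- edge_offset + seq_len(rect_px[1])
  if (max(rows) > d[1]) stop("rectangle does not fit below the FOV edge",
                             call. = FALSE)
  w <- rect_px[2]
  band <- unique(c(seq_len(min(edge_band, d[3])),
                   seq.int(max(1L, d[3] - edge_band + 1L), d[3])))
  with_seed(seed, {
    elig <- lapply(seq_len(d[3]), function(z) integer(0))
    for (z in band) {
      col_ok <- colSums(!tissue_mask[rows, , z, drop = FALSE]) == 0L
      if (!any(col_ok) || d[2] < w) next
      run <- vapply(seq_len(d[2] - w + 1L),
                    function(c0) all(col_ok[c0:(c0 + w - 1L)]), TRUE)
      elig[[z]] <- which(run)
    }
    slices_ok <- which(vapply(elig, length, 1L) > 0L)
    if (length(slices_ok) == 0L)
      stop("no edge slice admits a tissue-confined rectangle", call. = FALSE)
    slices <- select_gapped_slices(slices_ok, n, min_slice_gap)
    lapply(slices, function(z) {
      c0 <- elig[[z]][sample.int(length(elig[[z]]), 1L)]
      roi_rect(z, c(rows[1], c0), rect_px[1], w)
    })
  })
}

#' Lesion SUVmax and SUVpeak
#'
#' `suv_max` is the maximum over a 3-d volume of interest; ties are broken by
#' the lowest `(slice, row, col)` coordinate. `suv_peak` is the mean within a
#' circular 2-d ROI of `peak_diameter_mm` (default 10 mm) centred at the
#' maximum pixel on its slice; the ROI must fit inside the image grid.
#'
#' @param vol a [pet_volume()].
#' @param voi either a logical array of the volume's dimensions or an n x 3
#'   matrix of `(row, col, slice)` voxel coordinates.
#' @param peak_diameter_mm diameter of the SUVpeak ROI in mm.
#' @return A list with `suv_max`, `suv_peak` and `max_location`
#'   (`c(row, col, slice)`).
#' @export
measure_lesion <- function(vol, voi, peak_diameter_mm = 10) {
  stopifnot(inherits(vol, "pet_volume"))
  d <- dim(vol$values)
  if (is.array(voi) && is.logical(voi)) {
    stopifnot(identical(dim(voi), d))
    coords <- which(voi, arr.ind = TRUE)
  } else {
    coords <- as.matrix(voi)
  }
  if (nrow(coords) == 0L) stop("empty VOI", call. = FALSE)
  if (any(coords < 1) || any(coords[, 1] > d[1]) ||
      any(coords[, 2] > d[2]) || any(coords[, 3] > d[3]))
    stop("VOI extends outside the image grid", call. = FALSE)
  vals <- vol$values[coords]
  m <- max(vals)
  cand <- which(vals == m)
  ord <- order(coords[cand, 3], coords[cand, 1], coords[cand, 2])
  loc <- coords[cand[ord[1]], ]
  peak_roi <- roi_circle(loc[3], loc[1:2], peak_diameter_mm, vol$spacing)
  structure(list(suv_max = m,
                 suv_peak = mean(roi_values(vol, peak_roi)),
                 max_location = as.integer(loc)),
            class = "lesion_measurement")
}

#' Relative SUV difference against a reference
#'
#' `d = (suv_tgt - suv_ref) / suv_ref * 100` (%).
#'
#' @param suv_tgt target-image SUV (vectorised).
#' @param suv_ref reference-image SUV, strictly positive.
#' @return Relative difference(s) in percent.
#' @export
relative_difference <- function(suv_tgt, suv_ref) {
  if (any(suv_ref <= 0)) stop("`suv_ref` must be > 0", call. = FALSE)
  (suv_tgt - suv_ref) / suv_ref * 100
}

#' Bland-Altman bias and limits
#'
#' Summarises a set of relative differences by their mean (`bias`) and
#' `1.96 *` sample standard deviation (`limits`). The latter is what
#' agreement plots draw as the limits of agreement around the bias.
#'
#' @param ds numeric vector of relative differences (length >= 2).
#' @return A list with `bias` and `limits`.
#' @export
bland_altman <- function(ds) {
  if (length(ds) < 2L) stop("need at least two differences", call. = FALSE)
  list(bias = mean(ds), limits = 1.96 * sd(ds))
}

#' Paired comparison with Bonferroni correction
#'
#' Runs a two-sided paired t-test or Wilcoxon signed-rank test and applies a
#' Bonferroni correction: `p_adj = min(1, n_comparisons * p_raw)`. When every
#' paired difference is zero, the comparison is degenerate and reported as
#' non-significant with an explicit flag.
#'
#' @param a,b paired samples of equal length (>= 2).
#' @param test `"t"` or `"wilcoxon"`.
#' @param n_comparisons number of comparisons in the family (default 1).
#' @return A list with `test`, `p_raw`, `p_adj`, `significant` (at 0.05) and
#'   `degenerate`.
#' @export
paired_compare <- function(a, b, test = c("t", "wilcoxon"),
                           n_comparisons = 1) {
  test <- match.arg(test)
  if (length(a) != length(b) || length(a) < 2L)
    stop("`a` and `b` must be paired samples of equal length >= 2",
         call. = FALSE)
  if (all(a == b))
    return(list(test = test, p_raw = NA_real_, p_adj = NA_real_,
                significant = FALSE, degenerate = TRUE))
  p <- if (test == "t") t.test(a, b, paired = TRUE)$p.value
  else suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                    exact = FALSE)$p.value)
  p_adj <- min(1, n_comparisons * p)
  list(test = test, p_raw = p, p_adj = p_adj,
       significant = p_adj < 0.05, degenerate = FALSE)
}

#' Maximum intensity projection
#'
#' Pixelwise maximum of the volume along a view axis. With the default axis
#' mapping, the craniocaudal view projects along rows (axis 1) and the
#' mediolateral view along columns (axis 2) of the in-plane grid.
#'
#' @param vol a [pet_volume()].
#' @param view `"craniocaudal"` or `"mediolateral"`.
#' @param axis_map named integer vector mapping views to array axes.
#' @return A 2-d matrix of SUV maxima.
#' @export
mip <- function(vol, view = c("craniocaudal", "mediolateral"),
                axis_map = c(craniocaudal = 1L, mediolateral = 2L)) {
  stopifnot(inherits(vol, "pet_volume"))
  view <- match.arg(view)
  axis <- axis_map[[view]]
  if (!axis %in% 1:3) stop("view axis must map to 1, 2 or 3", call. = FALSE)
  apply(vol$values, setdiff(1:3, axis), max)
}

#' Render a MIP on an inverse grayscale window
#'
#' Maps SUV through the display window (default 0-4) to inverse grayscale:
#' 1 (white) at the window floor, 0 (black) at the ceiling, clamped outside.
#'
#' @param img 2-d matrix from [mip()].
#' @param window SUV display window `c(low, high)`.
#' @return A matrix of gray levels in `[0, 1]`.
#' @export
render_mip <- function(img, window = c(0, 4)) {
  g <- (img - window[1]) / (window[2] - window[1])
  1 - pmin(pmax(g, 0), 1)
}
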