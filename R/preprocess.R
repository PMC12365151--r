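## CT preprocessing: containers, isotropic resampling, HU windowing,
## dual-scale lesion-centred cropping, and flip augmentation with
## bounding-box adjustment.
##
## Coordinate conventions (used consistently across the package):
##  * voxel indices are 0-based; a bounding box is center + size;
##  * "voxel" frame means voxel-index coordinates of the volume at hand
##    (centers may be fractional);
##  * "relative" frame means coordinates divided by the crop shape, so all
##    six box values lie in [0, 1] (clamped when a box overflows the crop).

#' CT volume container
#'
#' A rank-3 scalar grid (Hounsfield units before windowing, `[0,1]` after)
#' with voxel spacing and world origin in millimetres.
#'
#' @param voxels Rank-3 numeric array.
#' @param spacing_mm Positive length-3 voxel spacing.
#' @param origin_mm Length-3 world coordinate of voxel (0,0,0).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("ct_volume(): voxels must be rank-3")
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("ct_volume(): spacing_mm must be three strictly positive numbers")
  }
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin_mm = as.double(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' 3D lesion bounding box
#'
#' Center + size box in a declared coordinate frame: `"voxel"` (voxel-index
#' coordinates of a volume) or `"relative"` (divided by the crop shape, all
#' values in `[0, 1]`).
#'
#' @param center,size Length-3 numeric vectors.
#' @param frame `"voxel"` or `"relative"`.
#' @return An object of class `bbox3d`.
#' @export
bbox3d <- function(center, size, frame = c("voxel", "relative")) {
  frame <- match.arg(frame)
  center <- as.double(center); size <- as.double(size)
  if (length(center) != 3L || length(size) != 3L) {
    stop("bbox3d(): center and size must have length 3")
  }
  if (any(!is.finite(c(center, size))) || any(size <= 0)) {
    stop("bbox3d(): size must be strictly positive and finite")
  }
  if (frame == "relative" &&
      (any(center < 0 | center > 1) || any(size > 1 + 1e-9))) {
    stop("bbox3d(): relative-frame coordinates must lie in [0, 1]")
  }
  structure(list(center = center, size = size, frame = frame),
            class = "bbox3d")
}

#' @export
print.bbox3d <- function(x, ...) {
  cat("<bbox3d ", x$frame, "> center (",
      paste(signif(x$center, 4), collapse = ", "), ") size (",
      paste(signif(x$size, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Resample a CT volume to a target voxel spacing
#'
#' Trilinear resampling onto an axis-aligned grid with the requested spacing
#' (default 1 mm isotropic, the resolution the model consumes). The output
#' shape per axis is `round(shape * spacing / target)`; the resampled grid is
#' corner-aligned with the input (output index i maps to input index
#' `i * target / spacing`), and coordinates beyond the input extent are
#' clamped to the boundary.
#'
#' @param volume A [ct_volume()] with known positive spacing.
#' @param target_spacing_mm Positive length-3 target spacing (default 1 mm).
#' @return A [ct_volume()] with `spacing_mm` equal to the target.
#' @export
resample_to_isotropic <- function(volume, target_spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(volume, "ct_volume"))
  target <- as.double(target_spacing_mm)
  if (length(target) != 3L || any(!is.finite(target)) || any(target <= 0)) {
    stop("resample_to_isotropic(): target spacing must be positive")
  }
  s <- volume$spacing_mm
  v <- volume$voxels
  if (any(!is.finite(v))) stop("resample_to_isotropic(): non-finite voxels")
  if (isTRUE(all.equal(s, target, tolerance = 1e-12))) {
    return(ct_volume(v, target, volume$origin_mm))
  }
  in_shape <- dim(v)
  out_shape <- pmax(1L, as.integer(round(in_shape * s / target)))

  ax <- lapply(1:3, function(a) {
    u <- (seq_len(out_shape[a]) - 1) * target[a] / s[a]
    u <- pmin(pmax(u, 0), in_shape[a] - 1)
    i0 <- pmin(floor(u), in_shape[a] - 1)
    i1 <- pmin(i0 + 1, in_shape[a] - 1)
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, w = u - i0)
  })
  out <- array(0, out_shape)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) ax[[1]]$i1 else ax[[1]]$i0
    iy <- if (cy) ax[[2]]$i1 else ax[[2]]$i0
    iz <- if (cz) ax[[3]]$i1 else ax[[3]]$i0
    wx <- if (cx) ax[[1]]$w else 1 - ax[[1]]$w
    wy <- if (cy) ax[[2]]$w else 1 - ax[[2]]$w
    wz <- if (cz) ax[[3]]$w else 1 - ax[[3]]$w
    w <- outer(outer(wx, wy), wz)
    if (any(w > 0)) out <- out + v[ix, iy, iz, drop = FALSE] * w
  }
  ct_volume(out, target, volume$origin_mm)
}

#' Rescale a voxel-frame bounding box across a change of voxel spacing
#'
#' Companion to [resample_to_isotropic()]: maps box coordinates from the
#' source grid to the resampled grid (`coord * spacing / target`).
#'
#' @param bbox A voxel-frame [bbox3d()].
#' @param spacing_mm Source voxel spacing.
#' @param target_spacing_mm Target voxel spacing.
#' @return A voxel-frame [bbox3d()] on the resampled grid.
#' @export
rescale_bbox <- function(bbox, spacing_mm, target_spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(bbox, "bbox3d"))
  if (bbox$frame != "voxel") stop("rescale_bbox(): bbox must be voxel-frame")
  f <- as.double(spacing_mm) / as.double(target_spacing_mm)
  bbox3d(bbox$center * f, bbox$size * f, frame = "voxel")
}

#' Window and normalize Hounsfield units
#'
#' Clips intensities to the lung window `[lo_hu, hi_hu]` (default
#' `[-1000, 400]` HU) and rescales linearly to `[0, 1]`.
#'
#' @param volume A [ct_volume()] in HU, or a numeric array.
#' @param lo_hu,hi_hu Window bounds, `hi_hu > lo_hu`.
#' @return Same type as the input, intensities in `[0, 1]`.
#' @export
window_and_normalize <- function(volume, lo_hu = -1000, hi_hu = 400) {
  if (hi_hu <= lo_hu) stop("window_and_normalize(): need hi_hu > lo_hu")
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  if (any(!is.finite(v))) stop("window_and_normalize(): non-finite voxels")
  v <- (pmin(pmax(v, lo_hu), hi_hu) - lo_hu) / (hi_hu - lo_hu)
  if (inherits(volume, "ct_volume")) {
    ct_volume(v, volume$spacing_mm, volume$origin_mm)
  } else {
    v
  }
}

#' Extract a fixed-shape crop centred on a lesion bounding box
#'
#' Crops a block of shape `crop_shape` centred on the (possibly fractional)
#' box center; regions falling outside the volume are padded with `pad`
#' (default 0, the post-windowing value of air at -1000 HU). The returned
#' box is converted to the crop-relative frame: `center' = (center -
#' origin) / crop_shape`, `size' = size / crop_shape`, clamped to `[0, 1]`.
#'
#' @param volume A [ct_volume()] (already windowed) or numeric array.
#' @param bbox Voxel-frame [bbox3d()] whose center lies inside the volume.
#' @param crop_shape Integer length-3 crop shape, e.g. `c(32, 32, 32)`.
#' @param pad Padding value for out-of-volume voxels.
#' @return A list with `grid` (the crop), `bbox` (crop-relative) and
#'   `origin` (0-based voxel index of the crop's first voxel).
#' @export
crop_centered_roi <- function(volume, bbox, crop_shape, pad = 0) {
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  stopifnot(inherits(bbox, "bbox3d"))
  if (bbox$frame != "voxel") {
    stop("crop_centered_roi(): bbox must be voxel-frame")
  }
  crop_shape <- as.integer(crop_shape)
  vol_shape <- dim(v)
  if (any(crop_shape < 1L)) stop("crop_centered_roi(): bad crop shape")
  if (any(crop_shape > 4L * vol_shape)) {
    stop("crop_centered_roi(): crop shape exceeds 4x the volume extent")
  }
  ctr <- bbox$center
  if (any(ctr < 0 | ctr > vol_shape - 1)) {
    stop("crop_centered_roi(): bbox center outside the volume")
  }
  origin <- as.integer(round(ctr - crop_shape / 2))
  grid <- array(pad, crop_shape)
  src_lo <- pmax(origin, 0L)
  src_hi <- pmin(origin + crop_shape - 1L, vol_shape - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - origin
    grid[(dst_lo[1] + 1):(dst_lo[1] + 1 + src_hi[1] - src_lo[1]),
         (dst_lo[2] + 1):(dst_lo[2] + 1 + src_hi[2] - src_lo[2]),
         (dst_lo[3] + 1):(dst_lo[3] + 1 + src_hi[3] - src_lo[3])] <-
      v[(src_lo[1] + 1):(src_hi[1] + 1),
        (src_lo[2] + 1):(src_hi[2] + 1),
        (src_lo[3] + 1):(src_hi[3] + 1)]
  }
  rel_center <- pmin(pmax((ctr - origin) / crop_shape, 0), 1)
  rel_size <- pmin(bbox$size / crop_shape, 1)
  list(grid = grid,
       bbox = bbox3d(rel_center, rel_size, frame = "relative"),
       origin = origin)
}

#' Convert a crop-relative box back to voxel coordinates
#'
#' Inverse of the relative-coordinate mapping of [crop_centered_roi()], given
#' the same crop geometry.
#'
#' @param bbox Crop-relative [bbox3d()].
#' @param origin 0-based voxel origin of the crop (as returned by
#'   [crop_centered_roi()]).
#' @param crop_shape The crop shape used.
#' @return A voxel-frame [bbox3d()].
#' @export
bbox_to_voxel <- function(bbox, origin, crop_shape) {
  stopifnot(inherits(bbox, "bbox3d"))
  if (bbox$frame != "relative") stop("bbox_to_voxel(): bbox must be relative")
  bbox3d(origin + bbox$center * crop_shape, bbox$size * crop_shape,
         frame = "voxel")
}

#' Mirror a crop and its bounding box along one axis
#'
#' Training-time augmentation: the grid is reversed along the given axis and
#' the relative box center reflected (`c <- 1 - c`); the box size is
#' unchanged. Applying the same flip twice is the identity.
#'
#' @param grid Rank-3 numeric array (a crop).
#' @param bbox Crop-relative [bbox3d()].
#' @param axis Axis to flip: 0, 1 or 2.
#' @return A list with the mirrored `grid` and adjusted `bbox`.
#' @export
flip_with_bbox <- function(grid, bbox, axis) {
  stopifnot(inherits(bbox, "bbox3d"))
  if (bbox$frame != "relative") {
    stop("flip_with_bbox(): bbox must be crop-relative")
  }
  if (!axis %in% 0:2) stop("flip_with_bbox(): axis must be 0, 1 or 2")
  d <- dim(grid)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis + 1L]] <- rev(idx[[axis + 1L]])
  grid <- grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  center <- bbox$center
  center[axis + 1L] <- 1 - center[axis + 1L]
  list(grid = grid, bbox = bbox3d(center, bbox$size, frame = "relative"))
}

#' Full CT preparation for one lesion
#'
#' Composes the preprocessing chain: resample to the target spacing,
#' window/normalize HU, and extract the two lesion-centred crops (default
#' 32x32x32 and 128x128x32) with crop-relative boxes.
#'
#' @param volume A [ct_volume()] in HU.
#' @param bbox Voxel-frame [bbox3d()] on `volume`'s grid.
#' @param crop_small,crop_large Crop shapes for the two scales.
#' @param target_spacing_mm Resampling target (default 1 mm isotropic).
#' @param lo_hu,hi_hu HU window.
#' @return A list with `roi_small`, `roi_large` (normalized grids),
#'   `bbox_small`, `bbox_large` (crop-relative) and the crop origins.
#' @export
preprocess_case <- function(volume, bbox,
                            crop_small = c(32, 32, 32),
                            crop_large = c(128, 128, 32),
                            target_spacing_mm = c(1, 1, 1),
                            lo_hu = -1000, hi_hu = 400) {
  res <- resample_to_isotropic(volume, target_spacing_mm)
  bb <- rescale_bbox(bbox, volume$spacing_mm, target_spacing_mm)
  res <- window_and_normalize(res, lo_hu, hi_hu)
  small <- crop_centered_roi(res, bb, crop_small)
  large <- crop_centered_roi(res, bb, crop_large)
  list(roi_small = small$grid, roi_large = large$grid,
       bbox_small = small$bbox, bbox_large = large$bbox,
       origin_small = small$origin, origin_large = large$origin)
}
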