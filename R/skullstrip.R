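#' Volume-preserving isotropic voxel size
#'
#' The isotropic spacing whose voxel volume equals that of the input spacing:
#' the cube root of the spacing product. For the common neonatal acquisition
#' spacing of 0.5 x 0.5 x 1.0 mm this is 0.63 mm.
#'
#' @param spacing voxel spacing in mm per axis.
#' @param digits decimals for the reported value (default 2, the convention
#'   used when naming resliced images).
#' @export
volume_preserving_spacing <- function(spacing, digits = 2) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values")
  round(prod(spacing)^(1 / 3), digits)
}

#' Refine an over-inclusive brain mask
#'
#' Minimises non-brain tissue (scalp, eyes, skull stripe) remaining in an
#' initial, deliberately conservative brain mask:
#'
#' 1. k-class K-means clustering of the T2 intensities inside the mask; the
#'    darkest class is background and is removed;
#' 2. binary opening with an `open_mm` spherical element to disconnect or
#'    remove outer bright stripes;
#' 3. retain the largest connected component;
#' 4. binary closing with a `close_mm` spherical element to smooth the mask
#'    boundary and close holes (hence `close_mm` > `open_mm`).
#'
#' When the intensities inside the mask have fewer than `k` distinct values,
#' a 2-class split is attempted instead; if that is also degenerate the
#' background-removal step is skipped.
#'
#' @param t2 T2-weighted intensity volume.
#' @param initial_mask nonempty binary mask sharing `t2`'s geometry.
#' @param k number of K-means classes (default 4).
#' @param open_mm,close_mm spherical element radii in mm (defaults 4 and 7).
#' @param seed passed to [kmeans_intensity()].
#' @return refined binary mask, same container type as `initial_mask`.
#' @export
refine_brain_mask <- function(t2, initial_mask, k = 4, open_mm = 4, close_mm = 7,
                              seed = 1) {
  stopifnot(is_vol(t2))
  check_same_geometry(t2, initial_mask)
  m0 <- mask_array(initial_mask)
  if (!any(m0)) stop("initial mask is empty")
  vals <- t2$data[m0]
  cls <- tryCatch(kmeans_intensity(vals, k = k, seed = seed), error = function(e) NULL)
  if (is.null(cls) && k != 2)
    cls <- tryCatch(kmeans_intensity(vals, k = 2, seed = seed), error = function(e) NULL)
  m <- m0
  if (!is.null(cls)) {
    keep <- cls != 0L
    m <- array(FALSE, dim(m0))
    m[m0][keep] <- TRUE
  }
  el_open <- spherical_element(open_mm, t2$spacing)
  m <- binary_opening(m, el_open)
  if (!any(m))
    stop("degenerate result: mask became empty after opening (open_mm = ",
         open_mm, " mm); the initial mask may be too thin")
  m <- largest_component(m, 26)
  m <- binary_closing(m, spherical_element(close_mm, t2$spacing))
  morph_wrap(initial_mask, m)
}

#' Crop to the mask bounding box and resample to isotropic voxels
#'
#' Crops `t2` to the bounding box of `mask` expanded by `pad_mm`, then
#' resamples to isotropic voxels of either the volume-preserving size or a
#' user-specified size. Intensities are interpolated trilinearly; a label
#' volume passed via `labels` is carried through the same geometry with
#' nearest-neighbour interpolation.
#'
#' @param t2 intensity volume.
#' @param mask nonempty binary mask on the same grid.
#' @param target_mm `"volume-preserving"` (default) or a positive isotropic
#'   voxel size in mm; `NA` skips resampling (crop only).
#' @param pad_mm padding added around the bounding box, in mm.
#' @param labels optional [label_volume()] resampled with nearest neighbour.
#' @return list of class `crop_result`: `cropped` (volume), `bbox` (3 x 2
#'   matrix of half-open 0-based voxel ranges), `new_spacing`, and `labels`
#'   when supplied.
#' @export
crop_and_resample <- function(t2, mask, target_mm = "volume-preserving",
                              pad_mm = 0, labels = NULL) {
  stopifnot(is_vol(t2))
  check_same_geometry(t2, mask)
  m <- mask_array(mask)
  if (!any(m)) stop("mask is empty")
  idx <- which(m, arr.ind = TRUE)
  pad_vox <- ceiling(pad_mm / t2$spacing)
  lo <- pmax(apply(idx, 2, min) - pad_vox, 1)
  hi <- pmin(apply(idx, 2, max) + pad_vox, dim(t2$data))
  bbox <- cbind(as.integer(lo - 1), as.integer(hi))  # half-open, 0-based
  crop <- t2$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab_crop <- if (!is.null(labels)) {
    check_same_geometry(t2, labels)
    labels$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  if (identical(target_mm, "volume-preserving"))
    target_mm <- volume_preserving_spacing(t2$spacing)
  if (is.na(target_mm)) {
    out <- neo_volume(crop, t2$spacing)
    res <- list(cropped = out, bbox = bbox, new_spacing = t2$spacing)
    if (!is.null(lab_crop))
      res$labels <- label_volume(lab_crop, t2$spacing, table = labels$table)
    class(res) <- "crop_result"
    return(res)
  }
  if (!is.numeric(target_mm) || target_mm <= 0)
    stop("target_mm must be positive, NA, or \"volume-preserving\"")
  in_sp <- t2$spacing
  d <- as.integer(dim(crop))
  odim <- as.integer(pmax(1, round(d * in_sp / target_mm)))
  osp <- rep(target_mm, 3)
  storage.mode(crop) <- "double"
  rs <- array(.cpp_resample(crop, d, in_sp, odim, osp, 0L), odim)
  res <- list(cropped = neo_volume(rs, osp), bbox = bbox, new_spacing = osp)
  if (!is.null(lab_crop)) {
    storage.mode(lab_crop) <- "double"
    lr <- array(as.integer(round(.cpp_resample(lab_crop, d, in_sp, odim, osp, 1L))),
                odim)
    res$labels <- label_volume(lr, osp, table = labels$table)
  }
  class(res) <- "crop_result"
  res
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result> bbox [%s] -> %s voxels at %s mm\n",
              paste(apply(x$bbox, 1, paste, collapse = ":"), collapse = ", "),
              paste(dim(x$cropped$data), collapse = " x "),
              paste(format(x$new_spacing, digits = 3), collapse = " x ")))
  invisible(x)
}
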