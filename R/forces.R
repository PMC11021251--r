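#' WM-region force image
#'
#' Signed force modulating white-surface deformation along the outward
#' normal: -1 (outward) inside the hemisphere WM labels, +1 (inward) in CSF
#' (voxels inside the brain left unlabelled by the regions image) and within
#' `decay_mm` of the brain-mask boundary, and a linear ramp (over `decay_mm`,
#' clamped to [-1, 1]) towards 0 elsewhere. Zero outside the brain mask.
#'
#' @param regions regions [label_volume()] (see [build_regions_image()]).
#' @param brain binary brain mask on the same grid.
#' @param decay_mm ramp length in mm (default 2).
#' @param scheme label scheme supplying the regions codes.
#' @return signed [neo_volume()]; positive drives the surface inward,
#'   negative outward.
#' @export
wm_region_force <- function(regions, brain, decay_mm = 2,
                            scheme = default_label_scheme()) {
  stopifnot(inherits(regions, "neo_labels"))
  check_same_geometry(regions, brain)
  b <- mask_array(brain)
  rg <- scheme$regions
  dat <- regions$data
  wm <- dat == rg$wm_lh | dat == rg$wm_rh
  csf <- b & dat == rg$background
  # brain boundary band: within decay_mm of the mask complement
  outside <- !b
  band <- if (any(outside)) {
    dist_out <- euclidean_distance(outside, regions$spacing)
    b & dist_out <= decay_mm
  } else array(FALSE, dim(b))
  pos <- csf | band
  f <- array(0, dim(b))
  if (any(pos)) {
    dp <- euclidean_distance(pos, regions$spacing)
    f <- f + pmax(0, 1 - dp / decay_mm)
  }
  if (any(wm)) {
    dw <- euclidean_distance(wm, regions$spacing)
    f <- f - pmax(0, 1 - dw / decay_mm)
  }
  f <- pmin(1, pmax(-1, f))
  f[pos] <- 1
  f[wm] <- -1  # WM membership wins over boundary proximity
  f[!b] <- 0
  neo_volume(array(f, dim(b)), spacing = regions$spacing,
             affine = regions$affine)
}

#' Thin-strand outward force
#'
#' An image-based outward force recovering thin strands of relatively bright
#' voxels (partial-volume-contaminated gyral WM) just outside the current WM
#' label, restricted to the pericalcarine zone where such penetration
#' failures concentrate (applying it globally causes errors elsewhere).
#' Candidates are locally bright voxels (negative second directional
#' derivative) outside the WM mask, within `depth_mm` of the WM boundary and
#' inside the pericalcarine mask dilated by `depth_mm`. The force is -1
#' (outward) on candidates and 0 elsewhere.
#'
#' @param t2 T2-weighted volume.
#' @param wm_mask current WM label mask.
#' @param pericalcarine pericalcarine cortex mask; when empty the force is
#'   identically zero (the fix is inactive).
#' @param sigma_mm derivative scale (default 0.6 mm: the targets are
#'   strands about one voxel wide, so the detection scale must sit at or
#'   below the voxel scale or the strand is averaged into its dark
#'   surroundings).
#' @param depth_mm search depth outside the WM boundary (default 2 mm).
#' @return signed [neo_volume()].
#' @export
thin_strand_force <- function(t2, wm_mask, pericalcarine, sigma_mm = 0.6,
                              depth_mm = 2) {
  stopifnot(is_vol(t2))
  check_same_geometry(t2, wm_mask)
  check_same_geometry(t2, pericalcarine)
  wm <- mask_array(wm_mask)
  pc <- mask_array(pericalcarine)
  out <- array(0, dim(wm))
  if (!any(pc) || !any(wm))
    return(with_geometry(out, t2))
  d2 <- directional_second_derivative(t2, sigma_mm)$data
  dw <- euclidean_distance(wm, t2$spacing)
  pc_d <- mask_array(binary_dilate(pc, spherical_element(depth_mm, t2$spacing)))
  cand <- (d2 < 0) & !wm & dw <= depth_mm & pc_d
  out[cand] <- -1
  with_geometry(out, t2)
}
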