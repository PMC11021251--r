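#' Interhemispheric fissure mask
#'
#' The fissure indentation is initialised as the voxels inside the convex
#' hull of the brain mask but not in the brain mask, then restricted to the
#' dilated, affine-transformed template fissure mask so that only the
#' occipital indentation is retained.
#'
#' @param brain nonempty binary brain mask.
#' @param template_fissure_warped template fissure mask already in subject
#'   space.
#' @param dilate_mm dilation applied to the template mask before
#'   intersection (default 5 mm; the restriction only needs to be coarse).
#' @return binary mask.
#' @export
make_fissure_mask <- function(brain, template_fissure_warped, dilate_mm = 5) {
  check_same_geometry(brain, template_fissure_warped)
  b <- mask_array(brain)
  if (!any(b)) stop("brain mask is empty")
  sp <- if (is_vol(brain)) brain$spacing else c(1, 1, 1)
  hull <- mask_array(convex_hull_mask(brain))
  cavity <- hull & !b
  tpl <- mask_array(template_fissure_warped)
  tpl <- mask_array(binary_dilate(tpl, spherical_element(dilate_mm, sp)))
  morph_wrap(brain, cavity & tpl)
}

#' Approximate cortical grey-matter mask
#'
#' Recovers the locally dark cortical ribbon while rejecting dark white
#' matter (periventricular stripes, hypointense spots) that a coarse tissue
#' segmentation confuses with cortex:
#'
#' 1. candidates are voxels with a positive second directional derivative
#'    (locally dark stripes);
#' 2. Canny edge voxels are removed, splitting ribbon from adjoining
#'    structures;
#' 3. each connected candidate component is scored by the fraction of its
#'    perimeter (6-connected exterior face-neighbours) that lies in the
#'    slightly dilated coarse GM label;
#' 4. components scoring at least `threshold` are kept.
#'
#' @param t2 T2-weighted volume.
#' @param tissue_gm coarse tissue-class GM mask (e.g. from an external
#'   tissue segmentation).
#' @param sigma_mm derivative/edge filter scale (default 1 mm).
#' @param neighbor_dilate_mm dilation of `tissue_gm` before perimeter
#'   scoring (default 1 mm).
#' @param threshold minimum perimeter fraction (default 0.2).
#' @param connectivity component connectivity for candidates (default 26).
#' @param grad_tol relative gradient tolerance for the "locally uniform"
#'   class (default 0.02 of the intensity range per mm): in noisy flat
#'   tissue the sign of the second derivative is meaningless, and without
#'   this class the candidate field percolates across structures.
#' @param edge_low_frac,edge_high_frac Canny hysteresis thresholds as
#'   fractions of the maximum gradient magnitude (defaults 0.7 and 0.85).
#'   Only the strongest boundaries (brain boundary, skull gap, ventricle
#'   walls) are removed: the cortical ribbon is itself bounded by moderate
#'   edges and is only a few voxels thick, so removing those would excise
#'   the ribbon the mask is meant to capture.
#' @return binary mask. Component scores are attached as attribute
#'   `"scores"`.
#' @export
make_gm_mask <- function(t2, tissue_gm, sigma_mm = 1, neighbor_dilate_mm = 1,
                         threshold = 0.2, connectivity = 26, grad_tol = 0.02,
                         edge_low_frac = 0.7, edge_high_frac = 0.85) {
  stopifnot(is_vol(t2))
  check_same_geometry(t2, tissue_gm)
  d2 <- directional_second_derivative(t2, sigma_mm, tol = grad_tol)
  cand <- d2$data > 0
  gmax <- max(image_gradient(t2, sigma_mm)$gmag$data)
  edges <- edge_mask(t2, low = edge_low_frac * gmax,
                     high = edge_high_frac * gmax, sigma_mm = sigma_mm)
  cand <- cand & !mask_array(edges)
  gm_d <- mask_array(binary_dilate(mask_array(tissue_gm),
                                   spherical_element(neighbor_dilate_mm, t2$spacing)))
  cc <- connected_components(cand, connectivity)
  lab <- cc$labels
  ncomp <- length(cc$sizes)
  out <- array(FALSE, dim(cand))
  scores <- numeric(ncomp)
  if (ncomp > 0) {
    per <- component_perimeter_fractions(lab, ncomp, gm_d)
    scores <- per
    keep <- which(per >= threshold)
    if (length(keep)) out <- array(lab %in% keep, dim(lab))
  }
  res <- morph_wrap(tissue_gm, out)
  attr(res, "scores") <- scores
  res
}

# internal: for each component code 1..ncomp of `lab`, the fraction of its
# perimeter voxels (6-connected exterior face neighbours, each counted once
# per component) lying in `target`. Components with no in-grid perimeter
# score 0.
component_perimeter_fractions <- function(lab, ncomp, target) {
  d <- dim(lab)
  frac <- numeric(ncomp)
  idx_all <- which(lab > 0)
  if (!length(idx_all)) return(frac)
  ai <- arrayInd(idx_all, d)
  comp <- lab[idx_all]
  pair_comp <- integer(0)
  pair_vox <- integer(0)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    ni <- ai[, 1] + shifts[s, 1]
    nj <- ai[, 2] + shifts[s, 2]
    nk <- ai[, 3] + shifts[s, 3]
    inside <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    lin <- ((nk[inside] - 1) * d[2] + (nj[inside] - 1)) * d[1] + ni[inside]
    cval <- comp[inside]
    ext <- lab[lin] != cval
    pair_comp <- c(pair_comp, cval[ext])
    pair_vox <- c(pair_vox, lin[ext])
  }
  if (!length(pair_comp)) return(frac)
  keep <- !duplicated(pair_comp * (prod(d) + 1) + pair_vox)
  pc <- pair_comp[keep]
  pv <- pair_vox[keep]
  tot <- tabulate(pc, nbins = ncomp)
  hit <- tabulate(pc[target[pv]], nbins = ncomp)
  frac[tot > 0] <- hit[tot > 0] / tot[tot > 0]
  frac
}

#' Septum pellucidum guide mask
#'
#' For each voxel of the warped template SP seed, marches laterally (away
#' from the midline, along -x for the left side and +x for the right) up to
#' `max_search_mm` and adds the first relatively dark voxel: one with a
#' positive Laplacian of Gaussian, or with intensity below the local
#' neighbourhood mean minus `tau`. Seeds with no dark voxel within range
#' contribute nothing.
#'
#' @param t2 T2-weighted volume.
#' @param template_sp_warped template-side SP seed mask in subject space.
#' @param max_search_mm maximal lateral search distance (default 10 mm).
#' @param side `"left"` or `"right"`.
#' @param sigma_mm LoG scale (default 1 mm).
#' @param tau darkness margin; default 0.5 x the intensity SD inside
#'   `brain` (or the whole volume when no brain mask is given).
#' @param brain optional brain mask for the tau default.
#' @param neigh_mm neighbourhood radius for the local mean (default 3 mm).
#' @return binary mask.
#' @export
make_sp_mask <- function(t2, template_sp_warped, max_search_mm = 10,
                         side = c("left", "right"), sigma_mm = 1, tau = NULL,
                         brain = NULL, neigh_mm = 3) {
  side <- match.arg(side)
  stopifnot(is_vol(t2))
  check_same_geometry(t2, template_sp_warped)
  seed <- mask_array(template_sp_warped)
  out <- array(FALSE, dim(seed))
  if (!any(seed)) return(morph_wrap(template_sp_warped, out))
  if (is.null(tau)) {
    vals <- if (!is.null(brain)) t2$data[mask_array(brain)] else as.vector(t2$data)
    tau <- 0.5 * stats::sd(vals)
  }
  lg <- laplacian_of_gaussian(t2, sigma_mm)$data
  # local mean over a box of half-width neigh_mm
  box <- t2
  for (ax in 1:3) {
    h <- max(1L, floor(neigh_mm / t2$spacing[ax]))
    k <- rep(1 / (2 * h + 1), 2 * h + 1)
    box$data <- array(.cpp_conv1d(box$data * 1.0, as.integer(dim(box$data)), k,
                                  ax - 1L), dim(box$data))
  }
  dark <- lg > 0 | t2$data < box$data - tau
  dirx <- if (side == "left") -1L else 1L
  steps <- 0:floor(max_search_mm / t2$spacing[1])
  idx <- which(seed, arr.ind = TRUE)
  found <- rep(FALSE, nrow(idx))
  hitx <- integer(nrow(idx))
  d <- dim(seed)
  for (s in steps) {
    x <- idx[, 1] + dirx * s
    ok <- !found & x >= 1 & x <= d[1]
    if (!any(ok)) break
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + x[ok]
    hit <- dark[lin]
    sel <- which(ok)[hit]
    found[sel] <- TRUE
    hitx[sel] <- x[ok][hit]
  }
  if (any(found)) {
    lin <- (idx[found, 3] - 1) * d[1] * d[2] + (idx[found, 2] - 1) * d[1] + hitx[found]
    out[lin] <- TRUE
  }
  morph_wrap(template_sp_warped, out)
}

#' Approximate lateral-ventricle mask
#'
#' Keeps the connected components of the coarse tissue-class ventricle label
#' that coincide with the majority-vote lateral-ventricle labels, then
#' removes relatively dark voxels (positive Laplacian of Gaussian) and the
#' dark periventricular stripe.
#'
#' @param tissue_ventricles coarse ventricle mask.
#' @param majority_lv majority-vote lateral-ventricle mask in subject space.
#' @param t2 T2-weighted volume.
#' @param periventricular dark periventricular stripe mask.
#' @param sigma_mm LoG scale (default 1 mm).
#' @param connectivity component connectivity (default 26).
#' @export
make_ventricle_mask <- function(tissue_ventricles, majority_lv, t2,
                                periventricular, sigma_mm = 1, connectivity = 26) {
  stopifnot(is_vol(t2))
  check_same_geometry(t2, tissue_ventricles)
  check_same_geometry(t2, majority_lv)
  tv <- mask_array(tissue_ventricles)
  mv <- mask_array(majority_lv)
  cc <- connected_components(tv, connectivity)
  lab <- cc$labels
  keep <- sort(unique(lab[mv & lab > 0]))
  m <- array(lab %in% keep & lab > 0, dim(lab))
  lg <- laplacian_of_gaussian(t2, sigma_mm)$data
  m <- m & !(lg > 0)
  m <- m & !mask_array(periventricular)
  morph_wrap(tissue_ventricles, m)
}

#' Extra-cranial background band
#'
#' All voxels outside the brain mask within `width_mm` of its boundary; used
#' as an auxiliary training label so that label fusion can classify residual
#' non-brain voxels.
#'
#' @param brain binary brain mask.
#' @param width_mm band width in mm (default 3).
#' @export
make_extracranial_bg <- function(brain, width_mm = 3) {
  b <- mask_array(brain)
  sp <- if (is_vol(brain)) brain$spacing else c(1, 1, 1)
  if (width_mm <= 0 || !any(b))
    return(morph_wrap(brain, array(FALSE, dim(b))))
  dist <- euclidean_distance(b, sp)
  dist <- if (is_vol(dist)) dist$data else dist
  morph_wrap(brain, !b & dist <= width_mm + 1e-9)
}

#' Skull (bright non-brain stripe) label
#'
#' Locally bright voxels outside the brain mask: negative values of the
#' second directional derivative filter restricted to the mask complement.
#'
#' @param t2 T2-weighted volume.
#' @param brain binary brain mask.
#' @param sigma_mm filter scale (default 1 mm).
#' @export
make_skull_label <- function(t2, brain, sigma_mm = 1) {
  stopifnot(is_vol(t2))
  check_same_geometry(t2, brain)
  d2 <- directional_second_derivative(t2, sigma_mm)
  morph_wrap(brain, (d2$data < 0) & !mask_array(brain))
}

#' Assemble the registration-guide mask bundle
#'
#' Convenience wrapper producing every mask channel used to guide atlas
#' registration, plus the auxiliary non-brain training labels. The corpus
#' callosum channel is a passthrough of the warped majority-vote CC label.
#'
#' @param t2 T2-weighted volume.
#' @param brain brain mask.
#' @param tissue_gm,tissue_ventricles coarse tissue-class masks.
#' @param majority_lv,majority_cc warped majority-vote masks.
#' @param periventricular dark periventricular stripe mask.
#' @param template_fissure,template_sp_left,template_sp_right warped
#'   template masks.
#' @param params optional list overriding the per-mask defaults
#'   (`fissure_dilate_mm`, `gm_sigma_mm`, `gm_neighbor_dilate_mm`,
#'   `gm_threshold`, `sp_max_search_mm`, `bg_width_mm`, `skull_sigma_mm`).
#' @return named list of binary masks: `fissure`, `gm`, `sp_left`,
#'   `sp_right`, `ventricles`, `cc`, `extracranial_bg`, `skull`.
#' @export
make_mask_bundle <- function(t2, brain, tissue_gm, tissue_ventricles,
                             majority_lv, majority_cc, periventricular,
                             template_fissure, template_sp_left,
                             template_sp_right, params = list()) {
  p <- utils::modifyList(list(fissure_dilate_mm = 5, gm_sigma_mm = 1,
                              gm_neighbor_dilate_mm = 1, gm_threshold = 0.2,
                              sp_max_search_mm = 10, bg_width_mm = 3,
                              skull_sigma_mm = 1), params)
  list(
    fissure = make_fissure_mask(brain, template_fissure, p$fissure_dilate_mm),
    gm = make_gm_mask(t2, tissue_gm, p$gm_sigma_mm, p$gm_neighbor_dilate_mm,
                      p$gm_threshold),
    sp_left = make_sp_mask(t2, template_sp_left, p$sp_max_search_mm, "left",
                           brain = brain),
    sp_right = make_sp_mask(t2, template_sp_right, p$sp_max_search_mm, "right",
                            brain = brain),
    ventricles = make_ventricle_mask(tissue_ventricles, majority_lv, t2,
                                     periventricular),
    cc = majority_cc,
    extracranial_bg = make_extracranial_bg(brain, p$bg_width_mm),
    skull = make_skull_label(t2, brain, p$skull_sigma_mm)
  )
}
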