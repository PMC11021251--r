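#' GM-adaptive search-radius map
#'
#' The fusion search radius is `r_near` mm inside the dilated grey-matter
#' mask (where registration residuals are largest) and `r_far` mm elsewhere.
#'
#' @param gm grey-matter mask.
#' @param dilate_mm dilation of `gm` in mm (default 2).
#' @param r_near,r_far search radii in mm; `r_near >= r_far` (defaults 2
#'   and 1).
#' @return list of class `radius_map`: `near` (binary mask), `r_near`,
#'   `r_far`, and `radius` (numeric volume of per-voxel radii in mm).
#' @export
build_radius_map <- function(gm, dilate_mm = 2, r_near = 2, r_far = 1) {
  if (r_near < r_far) stop("r_near must be >= r_far")
  g <- mask_array(gm)
  sp <- if (is_vol(gm)) gm$spacing else c(1, 1, 1)
  near <- if (dilate_mm > 0 && any(g))
    mask_array(binary_dilate(g, spherical_element(dilate_mm, sp)))
  else g
  radius <- array(ifelse(near, r_near, r_far), dim(g))
  structure(list(near = near, r_near = r_near, r_far = r_far,
                 radius = radius, spacing = sp), class = "radius_map")
}

#' Pearson patch similarity
#'
#' Goodness-of-fit between two image patches of equal shape: the Pearson
#' correlation of the flattened values, with the convention that a constant
#' patch (zero variance) has similarity 0.
#'
#' @param a,b numeric vectors or arrays of identical length.
#' @return scalar in [-1, 1].
#' @export
patch_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("patch shapes differ")
  if (length(a) < 2) return(0)
  va <- stats::var(a); vb <- stats::var(b)
  if (!is.finite(va) || !is.finite(vb) || va <= 1e-12 || vb <= 1e-12) return(0)
  stats::cor(a, b)
}

# internal: box patch offsets of half-width patch_mm per axis
patch_offsets <- function(patch_mm, spacing, radius = TRUE) {
  eff <- if (radius) patch_mm else patch_mm / 2
  h <- pmax(0L, floor(eff / spacing))
  g <- as.matrix(expand.grid(i = -h[1]:h[1], j = -h[2]:h[2], k = -h[3]:h[3]))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Patch-based multi-atlas label fusion by similarity-weighted voting
#'
#' For every voxel, each atlas searches within its local radius (see
#' [build_radius_map()]) for the atlas patch best matching the target patch
#' (Pearson correlation; patches clipped at the volume border) and votes for
#' its label at the best location with weight `max(r, 0)^beta`. The fused
#' label is the weight-sum argmax (ties to the lowest code); when all
#' weights vanish the majority atlas label at the voxel wins. The search is
#' restricted to the dilated union of nonzero atlas labels; outside it, the
#' plain majority label is used (everything there is background in
#' practice).
#'
#' @param target target intensity volume.
#' @param atlases list of atlas members, each `list(intensity =, labels =)`,
#'   all sharing the target geometry.
#' @param patch_mm patch size in mm (default 2); interpreted as the box
#'   half-width per axis when `patch_is_radius` (default), or as the box
#'   width when not.
#' @param radius_map [build_radius_map()] result; when `NULL` a uniform
#'   `r_far = 1` mm map is used.
#' @param beta vote sharpening exponent (default 2); negative correlations
#'   get zero weight.
#' @param patch_is_radius see `patch_mm`.
#' @return list with `labels` ([label_volume()]) and `confidence`
#'   ([neo_volume()], winning weight fraction).
#' @export
fuse_labels <- function(target, atlases, patch_mm = 2, radius_map = NULL,
                        beta = 2, patch_is_radius = TRUE) {
  stopifnot(is_vol(target))
  if (!length(atlases)) stop("empty atlas set")
  for (a in atlases) {
    check_same_geometry(target, a$intensity)
    check_same_geometry(target, a$labels)
  }
  sp <- target$spacing
  d <- as.integer(dim(target$data))
  if (is.null(radius_map))
    radius_map <- build_radius_map(array(FALSE, dim(target$data)), 0,
                                   r_near = 1, r_far = 1)
  stopifnot(inherits(radius_map, "radius_map"))
  if (!identical(as.integer(dim(radius_map$near)), d))
    stop("radius map geometry mismatch")

  poff <- patch_offsets(patch_mm, sp, patch_is_radius)
  near_off <- spherical_element(radius_map$r_near, sp)$offsets
  far_off <- spherical_element(radius_map$r_far, sp)$offsets

  any_lab <- Reduce(`|`, lapply(atlases, function(a) a$labels$data != 0L))
  max_search <- max(abs(rbind(near_off, far_off)))
  compute <- if (any(any_lab))
    mask_array(binary_dilate(any_lab, iterations = max_search + 1L))
  else any_lab

  tdat <- target$data
  storage.mode(tdat) <- "double"
  ai <- lapply(atlases, function(a) {
    x <- a$intensity$data; storage.mode(x) <- "double"; x
  })
  al <- lapply(atlases, function(a) {
    x <- a$labels$data; storage.mode(x) <- "integer"; x
  })

  res <- .cpp_fuse(tdat, d, ai, al, poff, near_off, far_off,
                   as.vector(radius_map$near), as.vector(compute), beta)
  tabs <- unique(do.call(rbind, lapply(atlases, function(a) a$labels$table)))
  labs <- label_volume(array(res$labels, dim(target$data)), sp,
                       table = tabs, affine = target$affine)
  conf <- with_geometry(array(res$confidence, dim(target$data)), target)
  list(labels = labs, confidence = conf)
}
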