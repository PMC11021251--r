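#' Spherical structuring element in voxel offsets
#'
#' Builds the set of integer voxel offsets whose centre-to-centre distance
#' under the given spacing is at most `radius_mm` (no rounding of the radius;
#' anisotropic spacing supported). The origin is always included and the set
#' is symmetric under negation.
#'
#' @param radius_mm sphere radius in mm (> 0).
#' @param spacing voxel spacing in mm per axis.
#' @return Object of class `sph_element`: list with `radius_mm`, `spacing`
#'   and an n x 3 integer `offsets` matrix, ordered by distance from the
#'   origin (origin first), then lexicographically.
#' @export
spherical_element <- function(radius_mm, spacing = c(1, 1, 1)) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || !is.finite(radius_mm) ||
      radius_mm <= 0)
    stop("`radius_mm` must be a single positive number")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values")
  r <- floor(radius_mm / spacing)
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d <- sqrt((g$i * spacing[1])^2 + (g$j * spacing[2])^2 + (g$k * spacing[3])^2)
  keep <- d <= radius_mm + 1e-12
  g <- g[keep, , drop = FALSE]
  ord <- order(d[keep], g$k, g$j, g$i)
  off <- as.matrix(g[ord, , drop = FALSE])
  dimnames(off) <- NULL
  storage.mode(off) <- "integer"
  structure(list(radius_mm = radius_mm, spacing = spacing, offsets = off),
            class = "sph_element")
}

#' Unit 6-neighbourhood (face) structuring element
#'
#' The 7-offset cross used by iteration-counted morphology.
#' @export
cross_element <- function() {
  off <- rbind(c(0L, 0L, 0L),
               c(-1L, 0L, 0L), c(1L, 0L, 0L),
               c(0L, -1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, -1L), c(0L, 0L, 1L))
  structure(list(radius_mm = NA_real_, spacing = c(NA, NA, NA), offsets = off),
            class = "sph_element")
}

# internal: accept sph_element or raw offset matrix
element_offsets <- function(element) {
  if (inherits(element, "sph_element")) element$offsets
  else {
    stopifnot(is.matrix(element), ncol(element) == 3)
    storage.mode(element) <- "integer"
    element
  }
}

# internal: run one morphology primitive and re-wrap the result
morph_wrap <- function(mask, out_data) {
  if (is_vol(mask)) { mask$data <- out_data; mask } else out_data
}

#' Binary dilation
#'
#' Either by a structuring element, or (when `iterations` is given) by N
#' applications of the unit 6-neighbourhood cross.
#'
#' @param mask binary mask (logical array or [neo_volume()]).
#' @param element [spherical_element()] or n x 3 integer offset matrix.
#' @param iterations alternative to `element`: number of unit-cross passes.
#' @export
binary_dilate <- function(mask, element = NULL, iterations = NULL) {
  m <- mask_array(mask)
  d <- as.integer(dim(m))
  if (!is.null(iterations)) {
    off <- cross_element()$offsets
    for (t in seq_len(iterations)) m <- array(.cpp_dilate(m, d, off), dim(m))
  } else {
    m <- array(.cpp_dilate(m, d, element_offsets(element)), dim(m))
  }
  morph_wrap(mask, m)
}

#' Binary erosion
#'
#' Voxels outside the grid count as background (objects touching the border
#' are eroded there).
#' @inheritParams binary_dilate
#' @export
binary_erode <- function(mask, element = NULL, iterations = NULL) {
  m <- mask_array(mask)
  d <- as.integer(dim(m))
  if (!is.null(iterations)) {
    off <- cross_element()$offsets
    for (t in seq_len(iterations)) m <- array(.cpp_erode(m, d, off), dim(m))
  } else {
    m <- array(.cpp_erode(m, d, element_offsets(element)), dim(m))
  }
  morph_wrap(mask, m)
}

#' Binary opening (erosion then dilation)
#' @inheritParams binary_dilate
#' @export
binary_opening <- function(mask, element = NULL, iterations = NULL) {
  binary_dilate(binary_erode(mask, element, iterations), element, iterations)
}

#' Binary closing (dilation then erosion)
#'
#' Computed on a grid padded by the element extent, so the closing is
#' extensive (`mask` is always a subset of the result) even at the border.
#' @inheritParams binary_dilate
#' @export
binary_closing <- function(mask, element = NULL, iterations = NULL) {
  m <- mask_array(mask)
  if (!is.null(iterations)) {
    off <- cross_element()$offsets
    pad <- as.integer(iterations)
  } else {
    off <- element_offsets(element)
    pad <- max(abs(off))
  }
  d <- dim(m)
  big <- array(FALSE, d + 2L * pad)
  ix <- lapply(d, function(n) seq_len(n) + pad)
  big[ix[[1]], ix[[2]], ix[[3]]] <- m
  bd <- as.integer(dim(big))
  n_iter <- if (is.null(iterations)) 1L else as.integer(iterations)
  for (t in seq_len(n_iter)) big <- array(.cpp_dilate(big, bd, off), dim(big))
  for (t in seq_len(n_iter)) big <- array(.cpp_erode(big, bd, off), dim(big))
  morph_wrap(mask, big[ix[[1]], ix[[2]], ix[[3]]])
}

#' Connected components of a binary mask
#'
#' Components are coded in voxel scan order (the component containing the
#' first foreground voxel in scan order gets code 1), which fixes all
#' tie-breaks downstream.
#'
#' @param mask binary mask.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners); default 26,
#'   the standard foreground connectivity.
#' @return list with `labels` (integer array or [neo_volume()] matching the
#'   input type) and `sizes` (named integer vector, voxels per code).
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  m <- mask_array(mask)
  lab <- array(.cpp_components(m, as.integer(dim(m)), as.integer(connectivity)),
               dim(m))
  ncomp <- max(lab)
  sizes <- tabulate(lab, nbins = ncomp)
  if (length(sizes)) names(sizes) <- seq_along(sizes)
  list(labels = morph_wrap(mask, lab), sizes = sizes)
}

#' Retain the largest connected component
#'
#' Ties go to the component appearing first in voxel scan order.
#' @inheritParams connected_components
#' @export
largest_component <- function(mask, connectivity = 26) {
  cc <- connected_components(mask, connectivity)
  lab <- if (is_vol(cc$labels)) cc$labels$data else cc$labels
  if (!length(cc$sizes)) return(morph_wrap(mask, array(FALSE, dim(lab))))
  best <- which.max(cc$sizes)  # first maximum = lowest code = scan order
  morph_wrap(mask, lab == best)
}

#' Chessboard (Chebyshev) distance transform
#'
#' Per-voxel L-infinity distance in voxels to the nearest mask voxel
#' (0 on the mask). An empty mask yields all-`NA`.
#' @param mask binary mask.
#' @export
chessboard_distance <- function(mask) {
  m <- mask_array(mask)
  morph_wrap(mask, array(.cpp_chessboard_dt(m, as.integer(dim(m))), dim(m)))
}

#' Euclidean distance transform in mm
#'
#' Exact (separable squared-distance transform), anisotropic spacing
#' supported. An empty mask yields all-`NA`.
#' @param mask binary mask.
#' @param spacing voxel spacing in mm; taken from the volume when `mask` is a
#'   [neo_volume()].
#' @export
euclidean_distance <- function(mask, spacing = NULL) {
  m <- mask_array(mask)
  if (is.null(spacing))
    spacing <- if (is_vol(mask)) mask$spacing else c(1, 1, 1)
  d <- array(.cpp_euclidean_dt(m, as.integer(dim(m)), as.numeric(spacing)), dim(m))
  if (is_vol(mask)) neo_volume(d, spacing = spacing, affine = mask$affine) else d
}

# ---------------------------------------------------------------------------
# Gaussian filtering and mm-aware derivative filters

# internal: sampled Gaussian-family kernel for one axis.
# order 0: Gaussian (normalised to sum 1); order 1: first derivative of the
# Gaussian in mm^-1; order 2: second derivative in mm^-2. Derivative kernels
# share the order-0 normalisation so responses approximate true derivatives
# of the smoothed signal.
gauss_kernel <- function(sigma_mm, spacing_axis, order = 0) {
  if (sigma_mm <= 0) stop("sigma_mm must be > 0")
  h <- max(1L, ceiling(3 * sigma_mm / spacing_axis))
  x <- (-h:h) * spacing_axis
  g <- exp(-x^2 / (2 * sigma_mm^2))
  k <- switch(as.character(order),
              "0" = g / sum(g),
              "1" = (-x / sigma_mm^2) * g / sum(g),
              "2" = (x^2 / sigma_mm^4 - 1 / sigma_mm^2) * g / sum(g),
              stop("order must be 0, 1 or 2"))
  # derivative kernels must be DC-free or constants leak through
  if (order > 0) k <- k - mean(k)
  k
}

# internal: separable filtering with per-axis derivative orders
filter_separable <- function(vol, sigma_mm, orders) {
  stopifnot(is_vol(vol))
  a <- vol$data
  storage.mode(a) <- "double"
  d <- as.integer(dim(a))
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_mm, vol$spacing[ax], orders[ax])
    a <- array(.cpp_conv1d(a, d, rev(k), ax - 1L), dim(a))
  }
  with_geometry(a, vol)
}

#' Gaussian smoothing with mm-scaled sigma
#' @param vol intensity volume.
#' @param sigma_mm smoothing scale in mm.
#' @export
smooth_gaussian <- function(vol, sigma_mm) filter_separable(vol, sigma_mm, c(0, 0, 0))

#' Image gradient of the Gaussian-smoothed volume
#'
#' @inheritParams smooth_gaussian
#' @return list of volumes `gx`, `gy`, `gz` (mm^-1) and magnitude `gmag`.
#' @export
image_gradient <- function(vol, sigma_mm) {
  gx <- filter_separable(vol, sigma_mm, c(1, 0, 0))
  gy <- filter_separable(vol, sigma_mm, c(0, 1, 0))
  gz <- filter_separable(vol, sigma_mm, c(0, 0, 1))
  gmag <- with_geometry(sqrt(gx$data^2 + gy$data^2 + gz$data^2), vol)
  list(gx = gx, gy = gy, gz = gz, gmag = gmag)
}

#' Second derivative of a Gaussian along the image gradient direction
#'
#' At each voxel, the second directional derivative of the Gaussian-smoothed
#' image along the local gradient direction: positive where the image is
#' locally dark (a dark stripe such as the cortical grey-matter ribbon on
#' T2), negative where locally bright. At voxels whose gradient magnitude is
#' below `tol` times the intensity range the direction is undefined (this
#' happens at the exact centre line of a dark or bright sheet, where the
#' gradient vanishes by symmetry); there the total curvature (Laplacian) is
#' used instead, and when that too is below the tolerance the voxel is
#' classed locally uniform and returns 0.
#'
#' @param vol intensity volume.
#' @param sigma_mm Gaussian scale in mm (default 1).
#' @param tol relative tolerance for the locally-uniform class; default
#'   1e-6 of the intensity range.
#' @return signed [neo_volume()].
#' @export
directional_second_derivative <- function(vol, sigma_mm = 1, tol = 1e-6) {
  rng <- diff(range(vol$data))
  if (rng == 0)
    return(with_geometry(array(0, dim(vol$data)), vol))
  g <- image_gradient(vol, sigma_mm)
  hxx <- filter_separable(vol, sigma_mm, c(2, 0, 0))$data
  hyy <- filter_separable(vol, sigma_mm, c(0, 2, 0))$data
  hzz <- filter_separable(vol, sigma_mm, c(0, 0, 2))$data
  hxy <- filter_separable(vol, sigma_mm, c(1, 1, 0))$data
  hxz <- filter_separable(vol, sigma_mm, c(1, 0, 1))$data
  hyz <- filter_separable(vol, sigma_mm, c(0, 1, 1))$data
  gx <- g$gx$data; gy <- g$gy$data; gz <- g$gz$data
  m2 <- gx^2 + gy^2 + gz^2
  num <- gx^2 * hxx + gy^2 * hyy + gz^2 * hzz +
    2 * (gx * gy * hxy + gx * gz * hxz + gy * gz * hyz)
  thr <- (tol * rng)^2
  lg <- hxx + hyy + hzz
  fallback <- ifelse(abs(lg) < tol * rng, 0, lg)
  out <- ifelse(m2 < thr, fallback, num / pmax(m2, .Machine$double.xmin))
  with_geometry(array(out, dim(vol$data)), vol)
}

#' Laplacian of Gaussian
#'
#' mm-scaled; locally dark voxels (e.g. the septum pellucidum on T2) give
#' positive values, locally bright voxels negative values.
#' @inheritParams directional_second_derivative
#' @export
laplacian_of_gaussian <- function(vol, sigma_mm = 1) {
  hxx <- filter_separable(vol, sigma_mm, c(2, 0, 0))$data
  hyy <- filter_separable(vol, sigma_mm, c(0, 2, 0))$data
  hzz <- filter_separable(vol, sigma_mm, c(0, 0, 2))$data
  with_geometry(hxx + hyy + hzz, vol)
}

#' K-means clustering of intensities, classes ordered dark to bright
#'
#' A deterministic wrapper around [stats::kmeans()] with k-means++-style
#' seeding: initial centres are drawn with squared-distance weighting from
#' the sorted values under a fixed seed (several restarts, best
#' within-cluster sum of squares kept). Sorting first makes the result
#' independent of input ordering, and squared-distance seeding makes it
#' equivariant under adding a constant. Classes are relabelled so class 0
#' has the darkest mean; assignment ties go to the lower class index.
#'
#' @param values numeric vector (length >= k).
#' @param k number of classes (>= 2).
#' @param seed seed for the (deterministic) centre seeding.
#' @param restarts number of k-means++ restarts (default 8).
#' @return integer vector of 0-based class assignments (0 = darkest class).
#' @export
kmeans_intensity <- function(values, k = 4, seed = 1, restarts = 8) {
  if (k < 2) stop("k must be >= 2")
  if (length(values) < k) stop("need at least k values")
  if (length(unique(values)) < k)
    stop("degenerate input: fewer than k distinct values")
  sv <- sort(values)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centres <- sv[sample.int(length(sv), 1)]
    dmin <- (sv - centres)^2
    while (length(centres) < k) {
      if (all(dmin == 0)) break
      nc <- sv[sample.int(length(sv), 1, prob = dmin)]
      centres <- c(centres, nc)
      dmin <- pmin(dmin, (sv - nc)^2)
    }
    if (length(centres) < k) next
    km <- tryCatch(
      stats::kmeans(values, centers = matrix(centres, ncol = 1),
                    iter.max = 100, algorithm = "Lloyd"),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  if (is.null(best)) stop("degenerate input: k-means failed to converge")
  km <- best
  ord <- order(km$centers[, 1])
  remap <- integer(k)
  remap[ord] <- seq_len(k) - 1L
  remap[km$cluster]
}

#' Convex hull mask
#'
#' Binary mask of voxels whose centres lie inside (or on) the 3D convex hull
#' of the input mask's voxel centres; always a superset of the input. Hull
#' vertices are found among the per-line x-extreme voxels, so the hull is
#' exact. Degenerate masks whose voxel centres span fewer than 3 dimensions
#' are returned unchanged.
#'
#' @param mask binary mask.
#' @export
convex_hull_mask <- function(mask) {
  m <- mask_array(mask)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(morph_wrap(mask, m))
  pts <- idx - 1  # 0-based voxel coordinates = centres in voxel units
  # rank of the point cloud
  if (nrow(pts) >= 2) {
    ctr <- sweep(pts, 2, colMeans(pts))
    rank3 <- qr(ctr, tol = 1e-9)$rank
  } else rank3 <- 0
  if (nrow(pts) < 4 || rank3 < 3) return(morph_wrap(mask, m))
  # candidate hull vertices: min/max x voxel on every (y, z) line
  key <- paste(idx[, 2], idx[, 3])
  lo <- tapply(idx[, 1], key, min)
  hi <- tapply(idx[, 1], key, max)
  yz <- do.call(rbind, strsplit(names(lo), " "))
  cand <- rbind(cbind(as.integer(lo), as.integer(yz[, 1]), as.integer(yz[, 2])),
                cbind(as.integer(hi), as.integer(yz[, 1]), as.integer(yz[, 2])))
  cand <- unique(cand) - 1
  hull <- array(.cpp_hull_mask(cand * 1.0, as.integer(dim(m))), dim(m))
  morph_wrap(mask, hull | m)
}

#' 3D Canny edge detector
#'
#' Gaussian-derivative gradient, non-maximum suppression along the gradient
#' direction, and hysteresis thresholding (26-connected weak components are
#' kept when they contain a strong voxel). Thresholds are absolute gradient
#' magnitudes in intensity units per mm; when `NULL` they default to 0.25 and
#' 0.5 of the maximum gradient magnitude.
#'
#' @param vol intensity volume.
#' @param low,high hysteresis thresholds (low < high).
#' @param sigma_mm Gaussian scale in mm.
#' @return binary edge mask with the geometry of `vol`.
#' @export
edge_mask <- function(vol, low = NULL, high = NULL, sigma_mm = 1) {
  if (diff(range(vol$data)) == 0)
    return(with_geometry(array(FALSE, dim(vol$data)), vol))
  g <- image_gradient(vol, sigma_mm)
  mx <- max(g$gmag$data)
  if (is.null(high)) high <- 0.5 * mx
  if (is.null(low)) low <- 0.5 * high
  if (mx <= 0) return(with_geometry(array(FALSE, dim(vol$data)), vol))
  d <- as.integer(dim(vol$data))
  nms <- array(.cpp_canny_nms(g$gmag$data, g$gx$data, g$gy$data, g$gz$data, d,
                              as.numeric(vol$spacing)), dim(vol$data))
  weak <- nms & g$gmag$data >= low
  strong <- nms & g$gmag$data >= high
  if (!any(strong)) return(with_geometry(array(FALSE, dim(vol$data)), vol))
  cc <- connected_components(weak, 26)
  lab <- cc$labels
  keep <- sort(unique(lab[strong]))
  keep <- keep[keep > 0]
  with_geometry(array(lab %in% keep, dim(lab)), vol)
}
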