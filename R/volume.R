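#' 3D scalar volume with voxel spacing
#'
#' The basic container used throughout the package: a 3D array (axis order
#' x: left-right, y: posterior-anterior, z: inferior-superior) together with
#' the voxel spacing in mm per axis. Intensity volumes hold doubles, masks
#' hold logicals, label volumes hold non-negative integers (see
#' [label_volume()]).
#'
#' @param data 3D array (numeric, integer or logical).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param affine optional 4x4 NIfTI affine carried through I/O; not used in
#'   computation.
#' @return An object of class `neo_volume`.
#' @export
neo_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "neo_volume")
}

#' 3D integer label volume with a label table
#'
#' @param data 3D array of non-negative integer codes.
#' @param spacing voxel spacing in mm.
#' @param table data.frame with columns `code` and `name` covering every
#'   nonzero code in `data`.
#' @param affine optional 4x4 affine.
#' @return An object of class `c("neo_labels", "neo_volume")`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), table = NULL, affine = NULL) {
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE))
    stop("label codes must be non-negative")
  v <- neo_volume(data, spacing, affine)
  codes <- sort(unique(as.vector(data)))
  codes <- codes[codes != 0L]
  if (is.null(table))
    table <- data.frame(code = codes, name = paste0("label_", codes),
                        stringsAsFactors = FALSE)
  missing <- setdiff(codes, table$code)
  if (length(missing))
    stop("codes absent from label table: ", paste(missing, collapse = ", "))
  v$table <- table
  class(v) <- c("neo_labels", "neo_volume")
  v
}

#' @export
print.neo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<neo_volume> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(format(x$spacing, digits = 3), collapse = " x "),
              typeof(x$data)))
  rng <- suppressWarnings(range(x$data, na.rm = TRUE))
  cat(sprintf("  range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
print.neo_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<neo_labels> %d x %d x %d voxels, spacing %s mm, %d label codes\n",
              d[1], d[2], d[3], paste(format(x$spacing, digits = 3), collapse = " x "),
              nrow(x$table)))
  invisible(x)
}

#' @export
dim.neo_volume <- function(x) dim(x$data)

# internal: is `x` a neo_volume (any payload type)?
is_vol <- function(x) inherits(x, "neo_volume")

# internal: coerce mask input (logical array or neo_volume) to a logical array
mask_array <- function(mask) {
  m <- if (is_vol(mask)) mask$data else mask
  if (length(dim(m)) != 3L) stop("mask must be a 3D array or neo_volume")
  if (!is.logical(m)) m <- m != 0
  m
}

# internal: geometry of `x` as list(dim, spacing); masks may be bare arrays
geom_of <- function(x, default_spacing = c(1, 1, 1)) {
  if (is_vol(x)) list(dim = dim(x$data), spacing = x$spacing)
  else list(dim = dim(x), spacing = default_spacing)
}

#' Check that two volumes share grid and spacing
#'
#' @param a,b volumes (or bare arrays, which only have their dimensions
#'   compared).
#' @keywords internal
check_same_geometry <- function(a, b) {
  ga <- geom_of(a); gb <- geom_of(b)
  if (!identical(as.integer(ga$dim), as.integer(gb$dim)))
    stop("volume dimensions differ: ", paste(ga$dim, collapse = "x"), " vs ",
         paste(gb$dim, collapse = "x"))
  if (is_vol(a) && is_vol(b) && any(abs(ga$spacing - gb$spacing) > 1e-9))
    stop("voxel spacings differ")
  invisible(TRUE)
}

# internal: wrap an array in the geometry of an existing volume
with_geometry <- function(data, like) {
  neo_volume(data, spacing = like$spacing, affine = like$affine)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file via RNifti, preserving spacing and affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param labels read as an integer [label_volume()]?
#' @return [neo_volume()] or [label_volume()].
#' @export
read_volume <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- structure(RNifti::xform(img), class = NULL)
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  if (labels) label_volume(array(as.integer(round(arr)), dim(arr)),
                           spacing = sp, affine = aff)
  else neo_volume(arr, spacing = sp, affine = aff)
}

#' Write a volume as NIfTI
#'
#' Label and mask payloads are written as unsigned integers; intensity
#' payloads as 32-bit floats. The stored affine is the volume's own if
#' present, otherwise a diagonal affine from the spacing.
#'
#' @param vol [neo_volume()] (logical payloads are written as 0/1).
#' @param path output path; directories are created as needed.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_vol(vol))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  arr <- vol$data
  datatype <- "float"
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim(arr))
    datatype <- "uint8"
  } else if (is.integer(arr)) {
    datatype <- if (max(arr, 0L) > 65535L) "int32" else "uint16"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  if (!is.null(vol$affine))
    RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b binary masks (arrays or volumes).
#' @export
dice <- function(a, b) {
  ma <- mask_array(a); mb <- mask_array(b)
  s <- sum(ma) + sum(mb)
  if (s == 0) return(NA_real_)
  2 * sum(ma & mb) / s
}

#' Mirror a volume left-right
#'
#' Flips the x (left-right) axis; used for symmetry checks.
#' @param vol volume or array.
#' @export
mirror_lr <- function(vol) {
  if (is_vol(vol)) {
    vol$data <- vol$data[dim(vol$data)[1]:1, , , drop = FALSE]
    vol
  } else vol[dim(vol)[1]:1, , , drop = FALSE]
}

#' Reorient a volume by axis permutation and flips
#'
#' Reorders axes to the (x, y, z) = (left-right, posterior-anterior,
#' inferior-superior) convention without resampling. The permutation and
#' flips can be derived from a NIfTI affine with [radiological_axes()].
#'
#' @param vol [neo_volume()].
#' @param perm integer length-3 permutation of 1:3.
#' @param flip logical length-3; flip each (permuted) axis?
#' @export
reorient_volume <- function(vol, perm = 1:3, flip = c(FALSE, FALSE, FALSE)) {
  stopifnot(is_vol(vol), setequal(perm, 1:3))
  a <- aperm(vol$data, perm)
  for (ax in 1:3) if (flip[ax]) {
    idx <- rev(seq_len(dim(a)[ax]))
    a <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  }
  neo_volume(a, spacing = vol$spacing[perm], affine = NULL)
}

#' Axis permutation and flips implied by a NIfTI affine
#'
#' Maps each voxel axis to its dominant world axis so that, after
#' [reorient_volume()], axes run left-right / posterior-anterior /
#' inferior-superior.
#'
#' @param affine 4x4 matrix.
#' @return list with `perm` and `flip`.
#' @export
radiological_axes <- function(affine) {
  R <- affine[1:3, 1:3]
  world <- apply(abs(R), 2, which.max)
  if (length(unique(world)) != 3L)
    stop("affine does not have three distinct dominant axes")
  perm <- order(world)          # voxel axis feeding world axis 1, 2, 3
  signs <- R[cbind(world, 1:3)]
  list(perm = perm, flip = signs[perm] < 0)
}
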