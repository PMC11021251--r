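#' Default label scheme
#'
#' FreeSurfer-style codes for the structures handled by the post-correction
#' and regions-image stages, plus the manual-edit sentinels (254 for LH WM,
#' 255 for RH WM). Cortical parcels use DKT-style 1000/2000-offset codes;
#' the two parcels named here are the illustrative sulcal pair shipped with
#' [default_sulcal_pairs()].
#'
#' @return list of class `label_scheme` with named codes and grouped code
#'   vectors (`subcortical_absorb`, `cortical_gm_lh`, `cortical_gm_rh`,
#'   `regions`).
#' @export
default_label_scheme <- function() {
  s <- list(
    csf = 24L,
    wm_lh = 2L, wm_rh = 41L,
    gm_lh = 3L, gm_rh = 42L,
    brainstem_cerebellum = 16L,
    lv_lh = 4L, lv_rh = 43L,
    thalamus_lh = 10L, thalamus_rh = 49L,
    caudate_lh = 11L, caudate_rh = 50L,
    putamen_lh = 12L, putamen_rh = 51L,
    hippocampus_lh = 17L, hippocampus_rh = 53L,
    choroid_lh = 31L, choroid_rh = 63L,
    amygdala_lh = 18L, amygdala_rh = 54L,
    accumbens_lh = 26L, accumbens_rh = 58L,
    ventraldc_lh = 28L, ventraldc_rh = 60L,
    v3 = 14L,
    cc = 251L,
    sp_lh = 55L, sp_rh = 56L,
    periventricular_lh = 96L, periventricular_rh = 97L,
    pericalcarine_lh = 1021L, pericalcarine_rh = 2021L,
    superiortemporal_lh = 1030L, superiortemporal_rh = 2030L,
    supramarginal_lh = 1031L, supramarginal_rh = 2031L,
    skull = 165L, extracranial_bg = 258L,
    ribbon_lh = 2L, ribbon_rh = 41L,
    sentinel_lh = 254L, sentinel_rh = 255L
  )
  s$subcortical_absorb <- c(s$lv_lh, s$lv_rh, s$thalamus_lh, s$thalamus_rh,
                            s$caudate_lh, s$caudate_rh, s$putamen_lh,
                            s$putamen_rh, s$hippocampus_lh, s$hippocampus_rh,
                            s$choroid_lh, s$choroid_rh, s$amygdala_lh,
                            s$amygdala_rh, s$accumbens_lh, s$accumbens_rh,
                            s$ventraldc_lh, s$ventraldc_rh)
  s$cortical_gm_lh <- c(s$gm_lh, s$pericalcarine_lh, s$superiortemporal_lh,
                        s$supramarginal_lh)
  s$cortical_gm_rh <- c(s$gm_rh, s$pericalcarine_rh, s$superiortemporal_rh,
                        s$supramarginal_rh)
  s$regions <- list(background = 0L, brainstem_cerebellum = 16L,
                    cortical_gm = 3L, wm_lh = 2L, wm_rh = 41L,
                    lv_lh = 4L, lv_rh = 43L)
  class(s) <- "label_scheme"
  s
}

#' Label table for a scheme
#'
#' @param scheme [default_label_scheme()]-style scheme.
#' @return data.frame with `code` and `name`, one row per scalar code.
#' @export
scheme_table <- function(scheme = default_label_scheme()) {
  scal <- scheme[vapply(scheme, function(x) is.numeric(x) && length(x) == 1,
                        logical(1))]
  tab <- data.frame(code = as.integer(unlist(scal)), name = names(scal),
                    stringsAsFactors = FALSE)
  tab[!duplicated(tab$code), ]
}

#' Read / write a FreeSurfer-style label lookup table
#'
#' Whitespace-separated columns `code name R G B A`; lines starting with `#`
#' are comments.
#'
#' @param path file path.
#' @export
read_label_table <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  parts <- strsplit(trimws(ln), "\\s+")
  data.frame(code = as.integer(vapply(parts, `[`, "", 1)),
             name = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
}

#' @rdname read_label_table
#' @param table data.frame with `code` and `name`.
#' @export
write_label_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ln <- c("# code name R G B A",
          sprintf("%d\t%s\t%d\t%d\t%d\t0", table$code, table$name,
                  (table$code * 37) %% 256, (table$code * 91) %% 256,
                  (table$code * 151) %% 256))
  writeLines(ln, path)
  invisible(path)
}

#' Resolve manual-edit sentinel labels
#'
#' Sentinel codes 254 and 255 mark manually edited LH/RH white-matter voxels.
#' They are rewritten to the ordinary WM codes (2 and 41) and returned with a
#' protection mask; every later post-correction operation leaves protected
#' voxels untouched, so manual edits survive reprocessing.
#'
#' @param labels [label_volume()].
#' @param scheme label scheme.
#' @return list with `labels` (sentinels resolved) and `protected` (logical
#'   array).
#' @export
apply_sentinels <- function(labels, scheme = default_label_scheme()) {
  stopifnot(inherits(labels, "neo_labels"))
  dat <- labels$data
  prot <- dat == scheme$sentinel_lh | dat == scheme$sentinel_rh
  dat[dat == scheme$sentinel_lh] <- scheme$wm_lh
  dat[dat == scheme$sentinel_rh] <- scheme$wm_rh
  out <- label_volume(dat, labels$spacing, table = scheme_table(scheme),
                      affine = labels$affine)
  list(labels = out, protected = prot)
}

# internal: largest WM component per hemisphere; list(lh =, rh =) logical
# arrays (empty when a hemisphere has no WM)
main_wm_components <- function(dat, scheme) {
  out <- list()
  for (side in c("lh", "rh")) {
    code <- if (side == "lh") scheme$wm_lh else scheme$wm_rh
    m <- dat == code
    out[[side]] <- if (any(m)) mask_array(largest_component(m, 26))
    else array(FALSE, dim(dat))
  }
  out
}

#' Reassign CSF islands touching the main WM component
#'
#' Connected CSF components that are face-adjacent (6-connectivity) to the
#' largest WM component of a hemisphere are relabelled to that hemisphere's
#' WM; components touching both hemispheres' main components are split
#' voxel-wise by chessboard distance (ties to LH). Protected voxels are
#' never changed.
#'
#' @param labels [label_volume()].
#' @param scheme label scheme.
#' @param protected optional logical array of voxels to leave untouched.
#' @export
reassign_csf_islands <- function(labels, scheme = default_label_scheme(),
                                 protected = NULL) {
  stopifnot(inherits(labels, "neo_labels"))
  dat <- labels$data
  if (!any(dat == scheme$wm_lh | dat == scheme$wm_rh)) {
    warning("no WM labels present; CSF-island reassignment is a no-op")
    return(labels)
  }
  main <- main_wm_components(dat, scheme)
  csf <- dat == scheme$csf
  if (!any(csf)) return(labels)
  cc <- connected_components(csf, 26)
  lab <- cc$labels
  # face-adjacency of each CSF component to each main WM component
  touch <- function(wm) {
    if (!any(wm)) return(integer(0))
    grown <- mask_array(binary_dilate(wm, cross_element()))
    sort(unique(lab[grown & lab > 0]))
  }
  t_lh <- touch(main$lh)
  t_rh <- touch(main$rh)
  both <- intersect(t_lh, t_rh)
  only_lh <- setdiff(t_lh, both)
  only_rh <- setdiff(t_rh, both)
  if (length(only_lh)) dat[lab %in% only_lh] <- scheme$wm_lh
  if (length(only_rh)) dat[lab %in% only_rh] <- scheme$wm_rh
  if (length(both)) {
    d_lh <- chessboard_distance(main$lh)
    d_rh <- chessboard_distance(main$rh)
    sel <- lab %in% both
    dat[sel] <- ifelse(d_lh[sel] <= d_rh[sel], scheme$wm_lh, scheme$wm_rh)
  }
  if (!is.null(protected)) dat[protected] <- labels$data[protected]
  label_volume(dat, labels$spacing, table = labels$table, affine = labels$affine)
}

#' Illustrative sulcal label-pair list
#'
#' Pairs of cortical parcels whose shared sulcus is prone to WM
#' mislabelling; the full list is site configuration. The shipped default
#' contains the superior temporal / supramarginal pair for each hemisphere.
#'
#' @param scheme label scheme.
#' @return 2-column integer matrix, one pair per row.
#' @export
default_sulcal_pairs <- function(scheme = default_label_scheme()) {
  rbind(c(scheme$superiortemporal_lh, scheme$supramarginal_lh),
        c(scheme$superiortemporal_rh, scheme$supramarginal_rh))
}

#' Reset WM between unlike sulcal banks to CSF
#'
#' For each configured parcel pair (A, B), WM voxels lying in the overlap of
#' the dilations of A and B are reset to CSF: CSF between sulcal banks that
#' was mislabelled WM sits exactly in that overlap. Protected voxels are
#' never changed.
#'
#' @param labels [label_volume()].
#' @param pair_list 2-column matrix (or list of length-2 vectors) of parcel
#'   code pairs.
#' @param dilate_mm dilation radius in mm (default 1).
#' @param scheme label scheme.
#' @param protected optional logical array of voxels to leave untouched.
#' @export
split_sulcal_banks <- function(labels, pair_list = default_sulcal_pairs(),
                               dilate_mm = 1, scheme = default_label_scheme(),
                               protected = NULL) {
  stopifnot(inherits(labels, "neo_labels"))
  if (is.list(pair_list)) pair_list <- do.call(rbind, pair_list)
  dat <- labels$data
  el <- spherical_element(dilate_mm, labels$spacing)
  wm <- dat == scheme$wm_lh | dat == scheme$wm_rh
  for (r in seq_len(nrow(pair_list))) {
    a <- dat == pair_list[r, 1]
    b <- dat == pair_list[r, 2]
    if (!any(a) || !any(b)) next
    ov <- mask_array(binary_dilate(a, el)) & mask_array(binary_dilate(b, el))
    hit <- wm & ov
    if (!is.null(protected)) hit <- hit & !protected
    dat[hit] <- scheme$csf
  }
  label_volume(dat, labels$spacing, table = labels$table, affine = labels$affine)
}

#' Build the regions image for surface extraction
#'
#' Produces the label image required by deformable cortical surface
#' extraction: brainstem+cerebellum, cortical GM, left/right cortical WM and
#' left/right lateral ventricles. The left/right WM labels are made to meet
#' at the midline: the WM composite is the hemisphere WM labels, voxels
#' added by morphological closing (`close_iters` unit-cross iterations) of
#' the corpus callosum and thalamus labels, the subcortical absorption set
#' (lateral ventricles, thalamus, caudate, putamen, hippocampus, choroid
#' plexus, amygdala, accumbens, ventralDC) and the dilated
#' (`v3_dilate_iters`) 3rd ventricle. Each composite voxel is assigned to
#' the hemisphere whose warped majority-vote ribbon label has the lower
#' chessboard distance (ties to LH, the lower code). Cortical GM and
#' brainstem+cerebellum are passed through; lateral-ventricle voxels are
#' re-expressed with per-hemisphere ventricle codes on top of the assigned
#' hemisphere.
#'
#' @param labels post-corrected [label_volume()].
#' @param ribbon_warped [label_volume()] with LH/RH ribbon labels meeting at
#'   the midline (codes `ribbon_lh`, `ribbon_rh` of the scheme).
#' @param scheme label scheme.
#' @param close_iters closing iterations for CC + thalamus (default 25).
#' @param v3_dilate_iters dilation iterations for the 3rd ventricle
#'   (default 2).
#' @return [label_volume()] using the scheme's `regions` codes.
#' @export
build_regions_image <- function(labels, ribbon_warped,
                                scheme = default_label_scheme(),
                                close_iters = 25, v3_dilate_iters = 2) {
  stopifnot(inherits(labels, "neo_labels"))
  check_same_geometry(labels, ribbon_warped)
  dat <- labels$data
  rib <- ribbon_warped$data
  rib_lh <- rib == scheme$ribbon_lh
  rib_rh <- rib == scheme$ribbon_rh
  if (!any(rib_lh) || !any(rib_rh))
    stop("ribbon image must contain both hemisphere labels")

  wm <- dat == scheme$wm_lh | dat == scheme$wm_rh
  ct <- dat == scheme$cc | dat == scheme$thalamus_lh | dat == scheme$thalamus_rh
  closed_added <- if (any(ct))
    mask_array(binary_closing(ct, iterations = close_iters)) & !ct
  else array(FALSE, dim(dat))
  absorb <- array(dat %in% scheme$subcortical_absorb, dim(dat))
  v3 <- dat == scheme$v3
  v3_d <- if (any(v3)) mask_array(binary_dilate(v3, iterations = v3_dilate_iters))
  else v3
  composite <- wm | closed_added | absorb | v3_d | ct

  d_lh <- chessboard_distance(rib_lh)
  d_rh <- chessboard_distance(rib_rh)
  hemi_lh <- d_lh <= d_rh  # tie -> LH (lower code)

  rg <- scheme$regions
  out <- array(rg$background, dim(dat))
  gm <- array(dat %in% c(scheme$cortical_gm_lh, scheme$cortical_gm_rh), dim(dat))
  out[gm] <- rg$cortical_gm
  out[dat == scheme$brainstem_cerebellum] <- rg$brainstem_cerebellum
  out[composite & hemi_lh] <- rg$wm_lh
  out[composite & !hemi_lh] <- rg$wm_rh
  lv <- dat == scheme$lv_lh | dat == scheme$lv_rh
  out[lv & hemi_lh] <- rg$lv_lh
  out[lv & !hemi_lh] <- rg$lv_rh

  tab <- data.frame(code = as.integer(unlist(rg)), name = names(rg),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$code != 0L, ]
  label_volume(out, labels$spacing, table = tab, affine = labels$affine)
}

#' Full post-correction stage
#'
#' Applies, in order: sentinel resolution, CSF-island reassignment,
#' sulcal-bank splitting, and regions-image construction. Sentinel-derived
#' protection is honoured throughout.
#'
#' @inheritParams build_regions_image
#' @inheritParams split_sulcal_banks
#' @return list with `labels` (corrected labels), `protected`, and
#'   `regions`.
#' @export
postfix_labels <- function(labels, ribbon_warped,
                           scheme = default_label_scheme(),
                           pair_list = default_sulcal_pairs(scheme),
                           dilate_mm = 1, close_iters = 25,
                           v3_dilate_iters = 2) {
  st <- apply_sentinels(labels, scheme)
  fixed <- reassign_csf_islands(st$labels, scheme, protected = st$protected)
  fixed <- split_sulcal_banks(fixed, pair_list, dilate_mm, scheme,
                              protected = st$protected)
  regions <- build_regions_image(fixed, ribbon_warped, scheme, close_iters,
                                 v3_dilate_iters)
  list(labels = fixed, protected = st$protected, regions = regions)
}
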