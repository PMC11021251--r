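#' Phantom specification
#'
#' Parameters of the synthetic neonatal-T2 phantom. Intensities follow the
#' neonatal T2 contrast convention (unmyelinated WM bright, cortical GM a
#' dark stripe, CSF brightest); the absolute scale is arbitrary since every
#' downstream stage is contrast-driven. Defaults give at least 3 noise-SDs
#' of separation between adjacent class means.
#'
#' @param n grid size per axis in voxels (>= 48).
#' @param spacing isotropic voxel size in mm.
#' @param means named class mean intensities.
#' @param noise_sd additive Gaussian noise SD.
#' @param bias_amp amplitude of the smooth multiplicative bias field
#'   (fraction; <= 0.1).
#' @param folds number of sinusoidal gyral folds around each hemisphere.
#' @param fold_amp radial amplitude of the folding (fraction of the brain
#'   radius).
#' @param thin_width_mm width of the thin pericalcarine gyrus (< 2 voxels).
#' @param notch_depth_mm depth of the posterior interhemispheric fissure
#'   notch.
#' @param seed RNG seed; the phantom is bit-reproducible from its parameters.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n = 64, spacing = 1,
                         means = c(background = 10, skull = 90, csf = 100,
                                   gm = 40, wm = 70, ventricle = 100,
                                   periventricular = 30, thalamus = 55,
                                   brainstem = 50, sp = 30),
                         noise_sd = 3, bias_amp = 0.05, folds = 6,
                         fold_amp = 0.04, thin_width_mm = 1.2,
                         notch_depth_mm = 6, seed = 1) {
  if (n < 48) stop("grid too small to host all structures (need n >= 48)")
  if (spacing <= 0) stop("spacing must be positive")
  if (!(means["gm"] < means["wm"] && means["wm"] < means["csf"]))
    stop("class means must be ordered GM < WM < CSF")
  structure(list(n = as.integer(n), spacing = spacing, means = means,
                 noise_sd = noise_sd, bias_amp = bias_amp, folds = folds,
                 fold_amp = fold_amp, thin_width_mm = thin_width_mm,
                 notch_depth_mm = notch_depth_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the synthetic neonatal brain phantom
#'
#' Builds a two-hemisphere brain with a bright ellipsoidal WM core, a dark
#' sinusoidally folded cortical GM ribbon (including one thin gyrus in the
#' designated pericalcarine zone and one sulcal wedge separating two
#' cortical parcels), bright outer and interhemispheric CSF, bright lateral
#' ventricles ringed by a dark periventricular stripe, thalami, a corpus
#' callosum bridge, a 3rd ventricle, dark septum pellucidum slabs offset
#' laterally from their template seeds, a posterior interhemispheric
#' fissure notch, a bright extra-cranial skull shell with two thin scalp
#' bridges attached to the brain, smooth multiplicative bias and additive
#' Gaussian noise. All ground-truth masks and the coarse-tissue /
#' majority-vote stand-ins needed by the other stages are returned.
#'
#' @param spec [phantom_spec()].
#' @return list of class `phantom_truth`; see Details.
#' @details Components: `t2`, `labels`, `brain`, `init_mask` (brain dilated
#'   3 mm plus attached scalp fragments, emulating a conservative initial
#'   brain extraction), `tissue_gm` and `tissue_ventricles` (coarse
#'   stand-ins, the ventricle one deliberately containing a false-positive
#'   blob), `majority_lv`, `majority_cc`, `periventricular`, `ribbon`,
#'   `template_fissure`, `template_sp_left`, `template_sp_right`, `scheme`,
#'   `spec`, and `manifest` (voxel indices of the planted structures).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  s <- spec$spacing
  sch <- default_label_scheme()
  dims <- c(n, n, n)
  cv <- ((1:n) - (n + 1) / 2) * s
  DX <- array(rep(cv, times = n * n), dims)
  DY <- array(rep(rep(cv, each = n), times = n), dims)
  DZ <- array(rep(cv, each = n * n), dims)

  L <- n * s
  rx <- 0.36 * L; ry <- 0.40 * L; rz <- 0.34 * L
  rho <- sqrt((DX / rx)^2 + (DY / ry)^2 + (DZ / rz)^2)
  theta <- atan2(DZ, DY)
  M <- spec$fold_amp * sin(spec$folds * theta)
  rho_out <- 0.88 + M
  rho_in <- 0.76 + M

  E <- rho <= 1
  notch <- E & abs(DX) <= 1.5 * s & DY <= -(ry - spec$notch_depth_mm)
  brain <- E & !notch
  lh <- DX < 0

  lab <- array(0L, dims)
  # radial shells
  lab[brain & rho > rho_out] <- sch$csf
  gm_band <- brain & rho > rho_in & rho <= rho_out
  lab[gm_band & lh] <- sch$gm_lh
  lab[gm_band & !lh] <- sch$gm_rh
  wm_core <- brain & rho <= rho_in
  lab[wm_core & lh] <- sch$wm_lh
  lab[wm_core & !lh] <- sch$wm_rh
  # interhemispheric CSF and medial GM lining (keeps the main CSF component
  # off the WM so that CSF-island reassignment has a well-defined target)
  lab[brain & abs(DX) <= 1 * s & rho <= rho_out] <- sch$csf
  lining <- brain & abs(DX) > 1 * s & abs(DX) <= 2.5 * s & rho <= rho_out
  lab[lining & lh] <- sch$gm_lh
  lab[lining & !lh] <- sch$gm_rh

  # brainstem + cerebellum: an inferior blob spanning the midline
  bs <- brain & ((DX / (0.55 * rx))^2 + ((DY + 0.15 * ry) / (0.45 * ry))^2 +
                   ((DZ + 0.80 * rz) / (0.45 * rz))^2) <= 1
  lab[bs] <- sch$brainstem_cerebellum

  # cortical parcels flanking a sulcal wedge at a fold trough
  theta_s <- -pi / 12
  dth_s <- theta - theta_s
  r_loc <- 0.82 * sqrt(ry * rz)
  # sulcal wedge: narrow at its mouth, wider at depth, with a GM floor so
  # the sulcal CSF never face-touches WM
  w_wedge <- (0.6 * s + 10 * s * (rho_out - rho)) / r_loc
  # the 0.07 floor margin exceeds the largest per-voxel step of rho, so the
  # sulcal CSF can never land face-adjacent to WM under discretisation
  wedge <- brain & abs(DX) > 2.5 * s & rho > rho_in + 0.07 & rho <= rho_out &
    abs(dth_s) < w_wedge
  bankA <- lab %in% c(sch$gm_lh, sch$gm_rh) & !wedge &
    dth_s >= -0.45 & dth_s < 0 & abs(DX) > 2.5 * s & rho > rho_in + 0.07
  bankB <- lab %in% c(sch$gm_lh, sch$gm_rh) & !wedge &
    dth_s >= 0 & dth_s < 0.45 & abs(DX) > 2.5 * s & rho > rho_in + 0.07
  lab[wedge] <- sch$csf
  lab[bankA & lh] <- sch$superiortemporal_lh
  lab[bankA & !lh] <- sch$superiortemporal_rh
  lab[bankB & lh] <- sch$supramarginal_lh
  lab[bankB & !lh] <- sch$supramarginal_rh

  # pericalcarine zone on a posterior gyral crest (clear of the
  # brainstem/cerebellum blob), with a thin WM gyrus inside it
  theta_pc <- 3 * pi / 4  # crest of the folding sine
  dth_pc <- theta - theta_pc
  pc_zone <- lab %in% c(sch$gm_lh, sch$gm_rh) & abs(dth_pc) < 0.3 &
    abs(DX) > 2.5 * s
  lab[pc_zone & lh] <- sch$pericalcarine_lh
  lab[pc_zone & !lh] <- sch$pericalcarine_rh
  w_thin <- spec$thin_width_mm / (2 * r_loc)
  thin <- brain & rho > rho_in & rho <= rho_in + 0.06 & abs(dth_pc) < w_thin &
    abs(DX) > 0.17 * rx & abs(DX) <= 0.52 * rx
  lab[thin & lh] <- sch$wm_lh
  lab[thin & !lh] <- sch$wm_rh

  # Deep grey/CSF structures scale with the brain radius so that the dark
  # structures stay separated by bright tissue at every grid size (as in
  # real anatomy); only midline constructs and stripe thicknesses are
  # absolute.
  u <- rx
  ell <- function(cx, cy, cz, ax, ay, az)
    ((DX - cx) / ax)^2 + ((DY - cy) / ay)^2 + ((DZ - cz) / az)^2 <= 1
  lv_l <- ell(-0.38 * u, 0.09 * u, 0, 0.12 * u, 0.27 * u, 0.15 * u)
  lv_r <- ell(0.38 * u, 0.09 * u, 0, 0.12 * u, 0.27 * u, 0.15 * u)
  peri_l <- ell(-0.38 * u, 0.09 * u, 0, 0.12 * u + 1.4 * s,
                0.27 * u + 1.4 * s, 0.15 * u + 1.4 * s) & !lv_l
  peri_r <- ell(0.38 * u, 0.09 * u, 0, 0.12 * u + 1.4 * s,
                0.27 * u + 1.4 * s, 0.15 * u + 1.4 * s) & !lv_r
  # the stripe models the tapetum along the lateral extrema of the
  # ventricles; it stays well clear of the medial wall (it never abuts
  # cortex)
  lat_sup <- abs(DX) >= 0.44 * u
  peri_l <- peri_l & lab == sch$wm_lh & lat_sup
  peri_r <- peri_r & lab == sch$wm_rh & lat_sup
  lab[peri_l] <- sch$periventricular_lh
  lab[peri_r] <- sch$periventricular_rh
  lab[lv_l] <- sch$lv_lh
  lab[lv_r] <- sch$lv_rh
  # thalami flank the ventricles postero-inferiorly, separated from the
  # medial wall by a bright WM column (internal-capsule-like)
  th_l <- ell(-0.30 * u, -0.35 * u, -0.17 * u, 0.10 * u, 0.13 * u, 0.10 * u)
  th_r <- ell(0.30 * u, -0.35 * u, -0.17 * u, 0.10 * u, 0.13 * u, 0.10 * u)
  lab[th_l] <- sch$thalamus_lh
  lab[th_r] <- sch$thalamus_rh
  v3 <- abs(DX) <= 1.5 * s & abs(DY + 4 * s) <= 3 * s & abs(DZ + 4 * s) <= 2.5 * s
  lab[v3] <- sch$v3
  cc <- abs(DX) <= 5.5 * s & abs(DY - 6 * s) <= 4 * s & abs(DZ - 5 * s) <= 2.5 * s
  lab[cc] <- sch$cc
  # septum pellucidum: a bright CSF corridor flanks the midline in the SP
  # window (as between the lateral ventricles), with the dark SP slabs
  # offset 2 voxels laterally from the midline template seeds
  spwin <- abs(DY - 2 * s) <= 3 * s & DZ > -1 * s & DZ <= 2.4 * s
  lab[brain & abs(DX) <= 2 * s & spwin] <- sch$csf
  sp_l <- DX >= -3 * s & DX < -2 * s & spwin
  sp_r <- DX > 2 * s & DX <= 3 * s & spwin
  lab[sp_l] <- sch$sp_lh
  lab[sp_r] <- sch$sp_rh

  # skull shell and two thin bright scalp bridges touching the brain
  shell <- rho > 1.06 & rho <= 1.14
  lab[shell] <- sch$skull
  theta_b <- pi / 12  # gyral crest: scalp attaches at a surface bulge
  w_b <- 1.4 * s / r_loc
  bridge <- rho > 1 & rho <= 1.06 & abs(theta - theta_b) < w_b &
    abs(DX) > 0.35 * rx & abs(DX) <= 0.43 * rx
  lab[bridge] <- sch$skull

  # intensities from class means
  mu <- spec$means
  t2 <- array(mu[["background"]], dims)
  assign_mu <- function(codes, value) t2[array(lab %in% codes, dims)] <<- value
  assign_mu(sch$csf, mu[["csf"]])
  assign_mu(c(sch$gm_lh, sch$gm_rh, sch$pericalcarine_lh, sch$pericalcarine_rh,
              sch$superiortemporal_lh, sch$superiortemporal_rh,
              sch$supramarginal_lh, sch$supramarginal_rh), mu[["gm"]])
  assign_mu(c(sch$wm_lh, sch$wm_rh, sch$cc), mu[["wm"]])
  assign_mu(c(sch$lv_lh, sch$lv_rh, sch$v3), mu[["ventricle"]])
  assign_mu(c(sch$periventricular_lh, sch$periventricular_rh),
            mu[["periventricular"]])
  assign_mu(c(sch$thalamus_lh, sch$thalamus_rh), mu[["thalamus"]])
  assign_mu(sch$brainstem_cerebellum, mu[["brainstem"]])
  assign_mu(c(sch$sp_lh, sch$sp_rh), mu[["sp"]])
  assign_mu(sch$skull, mu[["skull"]])

  if (spec$bias_amp > 0)
    t2 <- t2 * (1 + spec$bias_amp * sin(pi * DX / L + 0.3) *
                  cos(pi * DZ / L - 0.2))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    t2 <- t2 + stats::rnorm(length(t2), 0, spec$noise_sd)
  }

  # stand-ins for external coarse tissue labelling and majority-vote labels
  gm_family <- c(sch$gm_lh, sch$gm_rh, sch$pericalcarine_lh,
                 sch$pericalcarine_rh, sch$superiortemporal_lh,
                 sch$superiortemporal_rh, sch$supramarginal_lh,
                 sch$supramarginal_rh)
  tissue_gm <- array(lab %in% gm_family, dims)
  lv_mask <- lab == sch$lv_lh | lab == sch$lv_rh
  fp_blob <- ell(0.43 * u, -0.52 * u, 0.26 * u, 1.6 * s, 1.6 * s, 1.6 * s)
  tissue_ventricles <- lv_mask | fp_blob
  majority_lv <- mask_array(binary_dilate(lv_mask, iterations = 1L))
  periventricular <- lab == sch$periventricular_lh | lab == sch$periventricular_rh

  ribbon_dat <- array(0L, dims)
  ribbon_dat[brain & lh] <- sch$ribbon_lh
  ribbon_dat[brain & !lh] <- sch$ribbon_rh

  template_fissure <- mask_array(binary_dilate(notch, iterations = 1L))
  template_sp_left <- DX >= -1 * s & DX < 0 & spwin
  template_sp_right <- DX > 0 & DX <= 1 * s & spwin

  sp3 <- rep(s, 3)
  brain_v <- neo_volume(brain, sp3)
  init_mask <- mask_array(binary_dilate(brain, spherical_element(3, sp3)))
  frag <- shell & abs(theta - theta_b) < 0.5 & abs(DX) > 0.26 * rx & abs(DX) <= 0.52 * rx
  init_mask <- init_mask | bridge | frag

  truth <- list(
    t2 = neo_volume(t2, sp3),
    labels = label_volume(lab, sp3, table = scheme_table(sch)),
    brain = brain_v,
    init_mask = neo_volume(init_mask, sp3),
    tissue_gm = neo_volume(tissue_gm, sp3),
    tissue_ventricles = neo_volume(tissue_ventricles, sp3),
    majority_lv = neo_volume(majority_lv, sp3),
    majority_cc = neo_volume(cc, sp3),
    periventricular = neo_volume(periventricular, sp3),
    ribbon = label_volume(ribbon_dat, sp3, table = scheme_table(sch)),
    template_fissure = neo_volume(template_fissure, sp3),
    template_sp_left = neo_volume(template_sp_left, sp3),
    template_sp_right = neo_volume(template_sp_right, sp3),
    scheme = sch,
    spec = spec,
    manifest = list(
      thin_gyrus = which(thin),
      skull_stripe = which(shell),
      bridges = which(bridge),
      scalp_fragments = which(frag),
      notch = which(notch),
      wedge = which(wedge),
      sp_true = which(sp_l | sp_r),
      fp_ventricle_blob = which(fp_blob)
    )
  )
  class(truth) <- "phantom_truth"
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s voxels at %g mm, %d labels, seed %d\n",
              paste(dim(x$t2$data), collapse = "x"), x$t2$spacing[1],
              nrow(x$labels$table), x$spec$seed))
  invisible(x)
}

#' Generate a registered atlas set from a phantom
#'
#' Emulates the residual misalignment left after atlas-to-subject
#' registration: each atlas is the phantom intensity/label pair deformed by
#' an independent smooth random displacement field (Gaussian-smoothed white
#' noise, 8 mm smoothing) of maximal magnitude `warp_mm`, with intensities
#' interpolated trilinearly, labels by nearest neighbour, and independent
#' Gaussian intensity noise added.
#'
#' @param truth [make_phantom()] output.
#' @param n number of atlases.
#' @param warp_mm maximal displacement magnitude in mm.
#' @param noise_sd intensity noise SD.
#' @param seed RNG seed.
#' @return list of atlas members `list(intensity =, labels =)`.
#' @export
make_atlas_set <- function(truth, n = 5, warp_mm = 1, noise_sd = 5, seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  set.seed(seed)
  dims <- dim(truth$t2$data)
  sp <- truth$t2$spacing
  d <- as.integer(dims)
  tdat <- truth$t2$data
  storage.mode(tdat) <- "double"
  ldat <- truth$labels$data
  storage.mode(ldat) <- "double"
  lapply(seq_len(n), function(a) {
    if (warp_mm > 0) {
      fields <- lapply(1:3, function(ax) {
        f <- neo_volume(array(stats::rnorm(prod(dims)), dims), sp)
        smooth_gaussian(f, 8)$data
      })
      mag <- sqrt(Reduce(`+`, lapply(fields, function(f) f^2)))
      # scale so half the volume saturates at warp_mm, then cap the
      # magnitude there: normalising by the absolute maximum would leave
      # the displacement sub-voxel almost everywhere
      scale <- warp_mm / max(stats::quantile(mag, 0.5), 1e-12)
      cap <- pmin(1, warp_mm / pmax(mag * scale, 1e-12))
      disp <- lapply(1:3, function(ax) fields[[ax]] * scale * cap / sp[ax])
    } else {
      disp <- lapply(1:3, function(ax) array(0, dims))
    }
    wi <- array(.cpp_warp(tdat, d, disp[[1]], disp[[2]], disp[[3]], 0L), dims)
    wl <- array(as.integer(round(.cpp_warp(ldat, d, disp[[1]], disp[[2]],
                                           disp[[3]], 1L))), dims)
    if (noise_sd > 0) wi <- wi + stats::rnorm(prod(dims), 0, noise_sd)
    list(intensity = neo_volume(wi, sp),
         labels = label_volume(wl, sp, table = truth$labels$table))
  })
}

#' Plant a known labelling error in the phantom truth
#'
#' Inserts one of the error patterns that the post-correction stage (or a
#' sentinel-marked manual edit) is designed to reverse, recording the
#' affected voxels so tests can assert exact round trips.
#'
#' @param truth [make_phantom()] output.
#' @param mode `"csf_island"` (CSF pocket inside deep LH WM),
#'   `"sulcal_bridge"` (inter-parcel sulcal CSF filled with WM), or
#'   `"pial5_occlusion"` (the thin pericalcarine gyrus strand relabelled as
#'   GM, occluding the WM surface); `"none"` returns the labels unchanged.
#' @param seed RNG seed used to jitter the island site.
#' @param dilate_mm sulcal-pair dilation radius used to plant the bridge
#'   (must match the one used by the corresponding fix).
#' @return list with `labels` (corrupted [label_volume()]), `voxels`
#'   (planted linear indices), and `mode`.
#' @export
corrupt_labels <- function(truth, mode = c("csf_island", "sulcal_bridge",
                                           "pial5_occlusion", "none"),
                           seed = 1, dilate_mm = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  mode <- match.arg(mode)
  sch <- truth$scheme
  lab <- truth$labels$data
  dims <- dim(lab)
  s <- truth$t2$spacing[1]
  voxels <- integer(0)
  if (mode == "csf_island") {
    set.seed(seed)
    n <- dims[1]
    cv <- ((1:n) - (n + 1) / 2) * s
    rx <- 0.36 * n * truth$t2$spacing[1]
    ctr <- c(-0.39, -0.52, 0.22) * rx + stats::runif(3, -1, 1) * s
    DX <- array(rep(cv, times = n * n), dims)
    DY <- array(rep(rep(cv, each = n), times = n), dims)
    DZ <- array(rep(cv, each = n * n), dims)
    ball <- (DX - ctr[1])^2 + (DY - ctr[2])^2 + (DZ - ctr[3])^2 <= (1.8 * s)^2
    voxels <- which(ball & lab == sch$wm_lh)
    lab[voxels] <- sch$csf
  } else if (mode == "sulcal_bridge") {
    el <- spherical_element(dilate_mm, truth$labels$spacing)
    a <- mask_array(binary_dilate(lab == sch$superiortemporal_lh, el))
    b <- mask_array(binary_dilate(lab == sch$supramarginal_lh, el))
    voxels <- which(a & b & lab == sch$csf)
    lab[voxels] <- sch$wm_lh
  } else if (mode == "pial5_occlusion") {
    voxels <- truth$manifest$thin_gyrus
    side_lh <- lab[voxels] == sch$wm_lh
    lab[voxels[side_lh]] <- sch$pericalcarine_lh
    lab[voxels[!side_lh]] <- sch$pericalcarine_rh
  }
  list(labels = label_volume(lab, truth$labels$spacing,
                             table = truth$labels$table),
       voxels = voxels, mode = mode)
}
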