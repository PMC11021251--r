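#' Pipeline configuration
#'
#' Holds the subject id, base directory, seed and per-stage parameter
#' overrides for [run_pipeline()]. The directory layout mirrors the staged
#' processing convention: `RawT2/<id>.nii.gz` for the input image,
#' `TissueSegMCRIBS/<id>/` for segmentation outputs and
#' `SurfReconDeformable/<id>/recon/regions.nii.gz` for the surface-
#' extraction input.
#'
#' @param subject subject id.
#' @param base_dir base directory.
#' @param seed integer seed used by every stochastic stage.
#' @param params named list of per-stage parameter blocks (`phantom`,
#'   `skullstrip`, `maskgen`, `fuse`, `postfix`, `forces`).
#' @export
pipeline_config <- function(subject, base_dir, seed = 1, params = list()) {
  structure(list(subject = subject, base_dir = base_dir, seed = as.integer(seed),
                 params = params), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields `subject`, `base_dir`, `seed`, `params`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(y$subject, y$base_dir %||% dirname(path), y$seed %||% 1,
                  y$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: canonical file paths for a subject
pipeline_paths <- function(cfg) {
  id <- cfg$subject
  b <- cfg$base_dir
  seg <- file.path(b, "TissueSegMCRIBS", id)
  list(
    raw_t2 = file.path(b, "RawT2", paste0(id, ".nii.gz")),
    phantom_dir = file.path(b, "Phantom", id),
    seg_dir = seg,
    brain_mask = file.path(seg, paste0(id, "_brain_mask.nii.gz")),
    t2_cropped = file.path(seg, paste0(id, "_t2_cropped.nii.gz")),
    mask_dir = file.path(seg, "masks"),
    atlas_dir = file.path(seg, "atlases"),
    fusion = file.path(seg, paste0(id, "_labelfusion_dkt.nii.gz")),
    fusion_edited = file.path(seg, paste0(id, "_labelfusion_dkt_edited.nii.gz")),
    recon_dir = file.path(b, "SurfReconDeformable", id, "recon"),
    regions = file.path(b, "SurfReconDeformable", id, "recon", "regions.nii.gz"),
    wm_force = file.path(b, "SurfReconDeformable", id, "recon",
                         "wm_force.nii.gz"),
    thin_force = file.path(b, "SurfReconDeformable", id, "recon",
                           "thin_strand_force.nii.gz"),
    status = file.path(b, paste0(id, "_status.tsv")),
    log_dir = file.path(b, "logs", id)
  )
}

# internal: append a stage record to the tab-delimited status table and write
# the per-stage provenance log (parameters, seed, input hashes)
log_stage <- function(cfg, stage, last_file, params, inputs = character(0)) {
  p <- pipeline_paths(cfg)
  dir.create(dirname(p$status), recursive = TRUE, showWarnings = FALSE)
  row <- sprintf("%s\t%s\t%s", cfg$subject, stage, last_file)
  cat(row, "\n", sep = "", file = p$status, append = TRUE)
  dir.create(p$log_dir, recursive = TRUE, showWarnings = FALSE)
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  yaml::write_yaml(list(stage = stage, seed = cfg$seed,
                        params = params %||% list(), inputs = hashes,
                        last_file = last_file),
                   file.path(p$log_dir, paste0(stage, ".yaml")))
  invisible(last_file)
}

# internal: stop with a stage-dependency error when a prerequisite is absent
require_files <- function(stage, files) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("stage '", stage, "' is missing prerequisite file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Run pipeline stages for a subject
#'
#' Executes the requested stage directives in canonical order: `phantom`
#' (input synthesis), `skullstrip`, `maskgen`, `fuse`, `postfix`, `forces`.
#' Every stage appends its last-written file to the subject's tab-delimited
#' status table so that failures are diagnosable, and writes a provenance
#' log (parameters, seed, input hashes). If the edited fusion output
#' (`*_labelfusion_dkt_edited.nii.gz`) is newer than the raw fusion output,
#' downstream stages consume the edited file and honour its sentinel labels.
#'
#' @param config [pipeline_config()] or path to a YAML configuration.
#' @param directives character vector of stages to run.
#' @return invisibly, a list with `status` (0 on success) and the path map.
#' @export
run_pipeline <- function(config,
                         directives = c("skullstrip", "maskgen", "fuse",
                                        "postfix", "forces")) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  stopifnot(inherits(cfg, "pipeline_config"))
  order <- c("phantom", "skullstrip", "maskgen", "fuse", "postfix", "forces")
  bad <- setdiff(directives, order)
  if (length(bad)) stop("unknown directive(s): ", paste(bad, collapse = ", "))
  stages <- order[order %in% directives]
  p <- pipeline_paths(cfg)
  sch <- default_label_scheme()
  for (stage in stages) {
    pars <- cfg$params[[stage]] %||% list()
    switch(stage,
      phantom = {
        spec <- do.call(phantom_spec,
                        utils::modifyList(list(seed = cfg$seed),
                                          pars[names(pars) %in%
                                                 names(formals(phantom_spec))]))
        truth <- make_phantom(spec)
        write_volume(truth$t2, p$raw_t2)
        for (nm in c("brain", "init_mask", "tissue_gm", "tissue_ventricles",
                     "majority_lv", "majority_cc", "periventricular",
                     "template_fissure", "template_sp_left", "template_sp_right"))
          write_volume(truth[[nm]], file.path(p$phantom_dir,
                                              paste0(nm, ".nii.gz")))
        write_volume(truth$labels, file.path(p$phantom_dir, "labels.nii.gz"))
        write_volume(truth$ribbon, file.path(p$phantom_dir, "ribbon.nii.gz"))
        atl <- make_atlas_set(truth,
                              n = pars$n_atlases %||% 5,
                              warp_mm = pars$warp_mm %||% 1,
                              noise_sd = pars$atlas_noise_sd %||% 5,
                              seed = cfg$seed + 1L)
        for (k in seq_along(atl)) {
          write_volume(atl[[k]]$intensity,
                       file.path(p$atlas_dir, sprintf("atlas%02d_t2.nii.gz", k)))
          write_volume(atl[[k]]$labels,
                       file.path(p$atlas_dir, sprintf("atlas%02d_labels.nii.gz", k)))
        }
        write_label_table(scheme_table(sch),
                          file.path(p$phantom_dir, "labels.txt"))
        last <- file.path(p$phantom_dir, "labels.txt")
        log_stage(cfg, stage, last, pars)
      },
      skullstrip = {
        init <- file.path(p$phantom_dir, "init_mask.nii.gz")
        require_files(stage, c(p$raw_t2, init))
        t2 <- read_volume(p$raw_t2)
        im <- read_volume(init)
        refined <- refine_brain_mask(t2, neo_volume(im$data != 0, im$spacing),
                                     k = pars$k %||% 4,
                                     open_mm = pars$open_mm %||% 4,
                                     close_mm = pars$close_mm %||% 7,
                                     seed = cfg$seed)
        write_volume(refined, p$brain_mask)
        cr <- crop_and_resample(t2, refined,
                                target_mm = pars$iso %||% "volume-preserving",
                                pad_mm = pars$pad_mm %||% 5)
        write_volume(cr$cropped, p$t2_cropped)
        log_stage(cfg, stage, p$t2_cropped, pars, c(p$raw_t2, init))
      },
      maskgen = {
        need <- c(p$raw_t2, p$brain_mask,
                  file.path(p$phantom_dir,
                            c("tissue_gm.nii.gz", "tissue_ventricles.nii.gz",
                              "majority_lv.nii.gz", "majority_cc.nii.gz",
                              "periventricular.nii.gz", "template_fissure.nii.gz",
                              "template_sp_left.nii.gz",
                              "template_sp_right.nii.gz")))
        require_files(stage, need)
        t2 <- read_volume(p$raw_t2)
        rd <- function(f) {
          v <- read_volume(file.path(p$phantom_dir, f))
          neo_volume(v$data != 0, v$spacing)
        }
        bm <- read_volume(p$brain_mask)
        bundle <- make_mask_bundle(
          t2, neo_volume(bm$data != 0, bm$spacing), rd("tissue_gm.nii.gz"),
          rd("tissue_ventricles.nii.gz"), rd("majority_lv.nii.gz"),
          rd("majority_cc.nii.gz"), rd("periventricular.nii.gz"),
          rd("template_fissure.nii.gz"), rd("template_sp_left.nii.gz"),
          rd("template_sp_right.nii.gz"), params = pars)
        for (nm in names(bundle))
          write_volume(bundle[[nm]], file.path(p$mask_dir,
                                               paste0(nm, ".nii.gz")))
        last <- file.path(p$mask_dir, "skull.nii.gz")
        log_stage(cfg, stage, last, pars, need)
      },
      fuse = {
        gm_path <- file.path(p$mask_dir, "gm.nii.gz")
        atl_t2 <- sort(Sys.glob(file.path(p$atlas_dir, "atlas*_t2.nii.gz")))
        atl_lab <- sort(Sys.glob(file.path(p$atlas_dir, "atlas*_labels.nii.gz")))
        require_files(stage, c(p$raw_t2, gm_path))
        if (!length(atl_t2))
          stop("stage 'fuse' is missing prerequisite file(s): ",
               file.path(p$atlas_dir, "atlas*_t2.nii.gz"), call. = FALSE)
        t2 <- read_volume(p$raw_t2)
        gm <- read_volume(gm_path)
        atlases <- Map(function(ti, li) list(intensity = read_volume(ti),
                                             labels = read_volume(li, labels = TRUE)),
                       atl_t2, atl_lab)
        rm_map <- build_radius_map(neo_volume(gm$data != 0, gm$spacing),
                                   dilate_mm = pars$gm_dilate_mm %||% 2,
                                   r_near = pars$r_near %||% 2,
                                   r_far = pars$r_far %||% 1)
        fused <- fuse_labels(t2, unname(atlases),
                             patch_mm = pars$patch_mm %||% 2,
                             radius_map = rm_map, beta = pars$beta %||% 2)
        write_volume(fused$labels, p$fusion)
        file.copy(p$fusion, p$fusion_edited, overwrite = TRUE)
        log_stage(cfg, stage, p$fusion_edited, pars, c(p$raw_t2, gm_path))
      },
      postfix = {
        rib_path <- file.path(p$phantom_dir, "ribbon.nii.gz")
        require_files(stage, c(p$fusion, rib_path))
        src <- p$fusion
        if (file.exists(p$fusion_edited) &&
            file.mtime(p$fusion_edited) >= file.mtime(p$fusion))
          src <- p$fusion_edited
        labels <- read_volume(src, labels = TRUE)
        labels <- label_volume(labels$data, labels$spacing,
                               table = scheme_table(sch))
        ribbon <- read_volume(rib_path, labels = TRUE)
        res <- postfix_labels(labels, ribbon, sch,
                              dilate_mm = pars$dilate_mm %||% 1,
                              close_iters = pars$close_iters %||% 25,
                              v3_dilate_iters = pars$v3_dilate_iters %||% 2)
        write_volume(res$labels, file.path(p$seg_dir,
                                           paste0(cfg$subject,
                                                  "_labelfusion_dkt_fixed.nii.gz")))
        write_volume(res$regions, p$regions)
        log_stage(cfg, stage, p$regions, pars, c(src, rib_path))
      },
      forces = {
        require_files(stage, c(p$regions, p$brain_mask, p$raw_t2))
        regions <- read_volume(p$regions, labels = TRUE)
        bm <- read_volume(p$brain_mask)
        t2 <- read_volume(p$raw_t2)
        brain <- neo_volume(bm$data != 0, bm$spacing)
        f1 <- wm_region_force(regions, brain,
                              decay_mm = pars$decay_mm %||% 2, scheme = sch)
        fixed_path <- file.path(p$seg_dir,
                                paste0(cfg$subject, "_labelfusion_dkt_fixed.nii.gz"))
        wm <- regions$data == sch$regions$wm_lh | regions$data == sch$regions$wm_rh
        pc <- if (file.exists(fixed_path)) {
          fx <- read_volume(fixed_path, labels = TRUE)
          fx$data == sch$pericalcarine_lh | fx$data == sch$pericalcarine_rh
        } else array(FALSE, dim(regions$data))
        f2 <- thin_strand_force(t2, neo_volume(wm, regions$spacing),
                                neo_volume(pc, regions$spacing),
                                sigma_mm = pars$sigma_mm %||% 1,
                                depth_mm = pars$depth_mm %||% 2)
        write_volume(f1, p$wm_force)
        write_volume(f2, p$thin_force)
        log_stage(cfg, stage, p$thin_force, pars, c(p$regions, p$brain_mask))
      })
  }
  invisible(list(status = 0L, paths = p))
}
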