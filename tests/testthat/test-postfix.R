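test_that("label scheme and lookup-table I/O round trip", {
  sch <- default_label_scheme()
  expect_identical(sch$sentinel_lh, 254L)
  expect_identical(sch$sentinel_rh, 255L)
  expect_identical(sch$wm_lh, 2L)
  expect_identical(sch$wm_rh, 41L)
  tab <- scheme_table(sch)
  expect_false(any(duplicated(tab$code)))
  tmp <- file.path(tempdir(), "lut.txt")
  write_label_table(tab, tmp)
  tab2 <- read_label_table(tmp)
  expect_identical(tab2$code, tab$code)
  expect_identical(tab2$name, tab$name)
})

test_that("sentinel resolution rewrites 254/255 to WM and protects voxels", {
  sch <- default_label_scheme()
  d <- c(4, 4, 4)
  all254 <- label_volume(array(254L, d), table = scheme_table(sch))
  st <- apply_sentinels(all254, sch)
  expect_true(all(st$labels$data == sch$wm_lh))
  expect_true(all(st$protected))

  none <- label_volume(array(c(2L, 41L, 24L, 0L), d), table = scheme_table(sch))
  st2 <- apply_sentinels(none, sch)
  expect_identical(st2$labels$data, none$data)
  expect_false(any(st2$protected))

  mix <- array(24L, d); mix[1, 1, 1] <- 254L; mix[2, 1, 1] <- 255L
  st3 <- apply_sentinels(label_volume(mix, table = scheme_table(sch)), sch)
  expect_identical(st3$labels$data[1, 1, 1], sch$wm_lh)
  expect_identical(st3$labels$data[2, 1, 1], sch$wm_rh)
  expect_equal(sum(st3$protected), 2)
  expect_equal(sum(st3$labels$data != mix), 2)
})

test_that("CSF islands are reassigned to the touching hemisphere WM", {
  sch <- default_label_scheme()
  d <- c(12, 8, 8)
  base <- array(0L, d)
  base[2:5, 2:7, 2:7] <- sch$wm_lh
  base[8:11, 2:7, 2:7] <- sch$wm_rh

  # enclosed pocket in LH WM
  lab <- base; lab[3:4, 4, 4] <- sch$csf
  fixed <- reassign_csf_islands(label_volume(lab, table = scheme_table(sch)), sch)
  expect_identical(fixed$data, base)

  # CSF component touching no WM stays
  lab2 <- base; lab2[1, 1, 1] <- sch$csf
  fixed2 <- reassign_csf_islands(label_volume(lab2, table = scheme_table(sch)), sch)
  expect_identical(fixed2$data, lab2)

  # bridge touching both hemispheres: split by chessboard distance
  lab3 <- base
  lab3[6:7, 2:7, 2:7] <- sch$csf
  fixed3 <- reassign_csf_islands(label_volume(lab3, table = scheme_table(sch)), sch)
  d_lh <- oracle_chessboard(base == sch$wm_lh)
  d_rh <- oracle_chessboard(base == sch$wm_rh)
  bridge <- lab3 == sch$csf
  want <- ifelse(d_lh <= d_rh, sch$wm_lh, sch$wm_rh)
  expect_identical(fixed3$data[bridge], as.integer(want[bridge]))

  # no WM at all: warning, no-op
  lab4 <- array(sch$csf, d)
  expect_warning(out4 <- reassign_csf_islands(
    label_volume(lab4, table = scheme_table(sch)), sch), "no-op")
  expect_identical(out4$data, lab4)

  # protected voxels never change
  prot <- array(FALSE, d); prot[3, 4, 4] <- TRUE
  fixed5 <- reassign_csf_islands(label_volume(lab, table = scheme_table(sch)),
                                 sch, protected = prot)
  expect_identical(fixed5$data[3, 4, 4], sch$csf)
})

test_that("sulcal-bank splitting resets WM between unlike parcels to CSF", {
  sch <- default_label_scheme()
  d <- c(10, 10, 10)
  lab <- array(0L, d)
  lab[2:4, 2:8, 2:8] <- sch$superiortemporal_lh
  lab[5, 2:8, 2:8] <- sch$wm_lh          # 1-voxel WM wall
  lab[6:8, 2:8, 2:8] <- sch$supramarginal_lh
  pairs <- rbind(c(sch$superiortemporal_lh, sch$supramarginal_lh))
  fixed <- split_sulcal_banks(label_volume(lab, table = scheme_table(sch)),
                              pairs, dilate_mm = 1, scheme = sch)
  expect_true(all(fixed$data[5, 2:8, 2:8] == sch$csf))
  expect_identical(fixed$data[lab != sch$wm_lh], lab[lab != sch$wm_lh])

  # parcels farther apart than twice the dilation: nothing changes
  lab2 <- array(0L, d)
  lab2[2, 2:8, 2:8] <- sch$superiortemporal_lh
  lab2[3:7, 2:8, 2:8] <- sch$wm_lh
  lab2[8, 2:8, 2:8] <- sch$supramarginal_lh
  fixed2 <- split_sulcal_banks(label_volume(lab2, table = scheme_table(sch)),
                               pairs, dilate_mm = 1, scheme = sch)
  expect_identical(fixed2$data, lab2)

  # a protected wall voxel stays WM
  prot <- array(FALSE, d); prot[5, 4, 4] <- TRUE
  fixed3 <- split_sulcal_banks(label_volume(lab, table = scheme_table(sch)),
                               pairs, dilate_mm = 1, scheme = sch,
                               protected = prot)
  expect_identical(fixed3$data[5, 4, 4], sch$wm_lh)
})

test_that("planted corruptions are exactly reversed (round trips)", {
  ph <- get_phantom(1)
  sch <- ph$scheme
  isl <- corrupt_labels(ph, "csf_island", seed = 4)
  expect_gt(length(isl$voxels), 0)
  expect_identical(reassign_csf_islands(isl$labels, sch)$data, ph$labels$data)

  br <- corrupt_labels(ph, "sulcal_bridge")
  expect_gt(length(br$voxels), 0)
  expect_identical(
    split_sulcal_banks(br$labels, default_sulcal_pairs(sch), 1, sch)$data,
    ph$labels$data)

  # the pial-occlusion fix is a manual sentinel edit
  oc <- corrupt_labels(ph, "pial5_occlusion")
  ed <- oc$labels$data
  lh <- ph$labels$data[oc$voxels] == sch$wm_lh
  ed[oc$voxels[lh]] <- sch$sentinel_lh
  ed[oc$voxels[!lh]] <- sch$sentinel_rh
  st <- apply_sentinels(label_volume(ed, ph$labels$spacing,
                                     table = scheme_table(sch)), sch)
  expect_identical(st$labels$data, ph$labels$data)

  expect_identical(corrupt_labels(ph, "none")$labels$data, ph$labels$data)
})

test_that("post-correction is idempotent and conserves untouched codes", {
  ph <- get_phantom(2)
  sch <- ph$scheme
  isl <- corrupt_labels(ph, "csf_island", seed = 9)
  once <- split_sulcal_banks(reassign_csf_islands(isl$labels, sch),
                             default_sulcal_pairs(sch), 1, sch)
  twice <- split_sulcal_banks(reassign_csf_islands(once, sch),
                              default_sulcal_pairs(sch), 1, sch)
  expect_identical(twice$data, once$data)
  # only CSF/WM voxels may change
  changed <- which(once$data != isl$labels$data)
  expect_true(all(isl$labels$data[changed] %in%
                    c(sch$csf, sch$wm_lh, sch$wm_rh)))
})

test_that("regions image splits the midline WM composite by ribbon distance", {
  sch <- default_label_scheme()
  d <- c(14, 10, 10)
  lab <- array(0L, d)
  lab[2:5, 2:9, 2:9] <- sch$wm_lh
  lab[10:13, 2:9, 2:9] <- sch$wm_rh
  lab[6:9, 4:6, 4:6] <- sch$cc            # midline bridge via CC
  lab[3, 3, 3] <- sch$thalamus_lh         # absorbed subcortical
  rib <- array(0L, d)
  rib[1:7, , ] <- sch$ribbon_lh
  rib[8:14, , ] <- sch$ribbon_rh
  rg <- build_regions_image(label_volume(lab, table = scheme_table(sch)),
                            label_volume(rib, table = scheme_table(sch)),
                            sch, close_iters = 2, v3_dilate_iters = 1)
  wm_l <- rg$data == sch$regions$wm_lh
  wm_r <- rg$data == sch$regions$wm_rh
  expect_false(any(wm_l & wm_r))
  expect_identical(unname(rg$data[3, 3, 3]), sch$regions$wm_lh) # thalamus absorbed
  # brute-force nearest-ribbon assignment on the composite
  d_lh <- oracle_chessboard(rib == sch$ribbon_lh)
  d_rh <- oracle_chessboard(rib == sch$ribbon_rh)
  comp <- wm_l | wm_r
  expect_identical(wm_l[comp], (d_lh <= d_rh)[comp])  # ties -> LH

  expect_error(build_regions_image(
    label_volume(lab, table = scheme_table(sch)),
    label_volume(array(0L, d), table = scheme_table(sch)), sch),
    "ribbon")
})

test_that("sentinel-protected voxels survive the whole post-correction", {
  ph <- get_phantom(1)
  sch <- ph$scheme
  oc <- corrupt_labels(ph, "pial5_occlusion")
  ed <- oc$labels$data
  lh <- ph$labels$data[oc$voxels] == sch$wm_lh
  ed[oc$voxels[lh]] <- sch$sentinel_lh
  ed[oc$voxels[!lh]] <- sch$sentinel_rh
  edited <- label_volume(ed, ph$labels$spacing, table = scheme_table(sch))
  res <- postfix_labels(edited, ph$ribbon, sch)
  expect_identical(res$labels$data[oc$voxels], ph$labels$data[oc$voxels])
  expect_true(all(res$protected[oc$voxels]))
  # regions carry the protected voxels as hemisphere WM
  expect_true(all(res$regions$data[oc$voxels] %in%
                    c(sch$regions$wm_lh, sch$regions$wm_rh)))
})
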