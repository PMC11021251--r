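test_that("fissure mask is the hull cavity restricted to the template", {
  # convex solid: no cavity, empty fissure mask
  d <- c(14, 14, 14)
  ai <- arrayInd(seq_len(prod(d)), d)
  ball <- array(sqrt(rowSums((ai - 7.5)^2)) <= 5, d)
  tpl <- array(TRUE, d)
  expect_false(any(make_fissure_mask(neo_volume(ball), neo_volume(tpl))$data))

  # phantom posterior notch recovered through the template restriction
  ph <- get_phantom(1)
  fis <- make_fissure_mask(ph$brain, ph$template_fissure)
  notch <- ph$manifest$notch
  expect_gte(sum(fis$data[notch]) / length(notch), 0.9)
  hull_diff <- mask_array(convex_hull_mask(ph$brain)) & !ph$brain$data
  expect_true(all(fis$data <= hull_diff))

  # template disjoint from the cavity -> empty
  far <- array(FALSE, dim(ph$brain$data)); far[1:2, 1:2, 1:2] <- TRUE
  expect_false(any(make_fissure_mask(ph$brain, neo_volume(far, ph$brain$spacing),
                                     dilate_mm = 1)$data))
  expect_error(make_fissure_mask(neo_volume(array(FALSE, d)), neo_volume(tpl)),
               "empty")
})

test_that("perimeter-fraction scoring matches a hand-counted oracle", {
  # dark plate inside bright tissue, coarse GM label overlapping one side
  for (seed in 1:6) {
    m <- rand_mask(c(6, 6, 6), p = 0.25, seed = seed)
    lab <- connected_components(m, 26)$labels
    tgt <- rand_mask(c(6, 6, 6), p = 0.4, seed = seed + 100)
    got <- neoseg:::component_perimeter_fractions(lab, max(lab), tgt)
    ref <- oracle_perimeter_fractions(lab, max(lab), tgt)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("GM mask keeps the ribbon, drops the periventricular stripe", {
  ph <- get_phantom(1, n = 96)
  gm <- make_gm_mask(ph$t2, ph$tissue_gm)
  truth <- ph$tissue_gm$data
  expect_gte(sum(gm$data & truth) / sum(truth), 0.8)
  expect_equal(sum(gm$data & ph$periventricular$data), 0)

  # output is a subset of the positive second-derivative candidates
  d2 <- directional_second_derivative(ph$t2, 1, tol = 0.02)
  expect_true(all(gm$data <= (d2$data > 0)))

  # monotone in the score threshold
  gm_strict <- make_gm_mask(ph$t2, ph$tissue_gm, threshold = 0.5)
  expect_true(all(gm_strict$data <= gm$data))

  # a dark plate fully embedded in the coarse GM label scores 1 and is
  # kept; with no coarse-GM contact it scores 0 and is dropped
  sc <- attr(gm, "scores")
  expect_true(any(sc == 0))
  d <- c(10, 10, 10)
  plate <- array(100, d); plate[5, 3:8, 3:8] <- 20
  vt <- neo_volume(plate)
  emb <- make_gm_mask(vt, array(plate < 50, d))
  expect_true(any(emb))
  expect_gte(max(attr(emb, "scores")), 0.99)
  iso <- make_gm_mask(vt, array(FALSE, d))
  expect_false(any(iso))
})

test_that("SP mask marches laterally to the first dark voxel", {
  d <- c(20, 9, 9)
  t2 <- array(100, d)
  seed <- array(FALSE, d)
  seed[10, 4:6, 4:6] <- TRUE

  # dark septum exactly under the seed -> output equals seed positions
  t2a <- t2; t2a[10, , ] <- 20
  spm <- make_sp_mask(neo_volume(t2a), seed, side = "left", tau = 10)
  expect_identical(which(spm != 0), which(seed))

  # septum offset 2 voxels laterally (left = -x) -> output shifted by 2
  t2b <- t2; t2b[8, , ] <- 20
  spm2 <- make_sp_mask(neo_volume(t2b), seed, side = "left", tau = 10)
  want <- array(FALSE, d); want[8, 4:6, 4:6] <- TRUE
  expect_identical(spm2 != 0, want)
  # the same septum is never found marching right
  spm3 <- make_sp_mask(neo_volume(t2b), seed, side = "right", tau = 10,
                       max_search_mm = 1)
  expect_false(any(spm3))

  # uniform bright image -> nothing found
  expect_false(any(make_sp_mask(neo_volume(t2), seed, side = "left", tau = 10)))

  # phantom: both sides land on the true dark slabs
  ph <- get_phantom(1)
  sch <- ph$scheme
  for (side in c("left", "right")) {
    tpl <- if (side == "left") ph$template_sp_left else ph$template_sp_right
    got <- make_sp_mask(ph$t2, tpl, side = side, brain = ph$brain)
    code <- if (side == "left") sch$sp_lh else sch$sp_rh
    expect_gt(sum(got$data), 0)
    # the lateral march may occasionally stop one voxel early on noise
    expect_gte(mean(ph$labels$data[got$data] == code), 0.85)
  }
})

test_that("SP search commutes with left-right mirroring", {
  ph <- get_phantom(2)
  got_l <- make_sp_mask(ph$t2, ph$template_sp_left, side = "left",
                        brain = ph$brain)
  t2m <- mirror_lr(ph$t2)
  tpl_m <- mirror_lr(ph$template_sp_left$data)
  got_m <- make_sp_mask(t2m, neo_volume(tpl_m, ph$t2$spacing), side = "right",
                        brain = neo_volume(mirror_lr(ph$brain$data),
                                           ph$t2$spacing))
  expect_identical(got_m$data, mirror_lr(got_l$data))
})

test_that("ventricle mask keeps coincident components and drops dark rims", {
  ph <- get_phantom(1)
  sch <- ph$scheme
  vent <- make_ventricle_mask(ph$tissue_ventricles, ph$majority_lv, ph$t2,
                              ph$periventricular)
  lv_true <- array(ph$labels$data %in% c(sch$lv_lh, sch$lv_rh),
                   dim(ph$labels$data))
  expect_gte(dice(vent$data, lv_true), 0.95)
  # the planted false-positive component does not coincide with the
  # majority-vote ventricles and is removed entirely
  expect_equal(sum(vent$data[ph$manifest$fp_ventricle_blob]), 0)
})

test_that("extracranial band and skull stripe labels", {
  d <- c(17, 17, 17)
  ai <- arrayInd(seq_len(prod(d)), d)
  ball <- array(sqrt(rowSums((ai - 9)^2)) <= 4, d)
  band <- make_extracranial_bg(neo_volume(ball, spacing = c(1, 1, 1)), 3)
  dist <- oracle_euclid(ball)
  expect_identical(band$data, !ball & dist <= 3)

  expect_false(any(make_extracranial_bg(neo_volume(array(TRUE, d)), 3)$data))
  expect_false(any(make_extracranial_bg(neo_volume(ball), 0)$data))

  ph <- get_phantom(1)
  sk <- make_skull_label(ph$t2, ph$brain)
  expect_gte(mean(sk$data[ph$manifest$skull_stripe]), 0.9)
  expect_equal(sum(sk$data & ph$brain$data), 0)  # restricted outside brain
})

test_that("maskgen outputs are invariant to a global intensity shift", {
  ph <- get_phantom(3)
  t2s <- neo_volume(ph$t2$data + 500, ph$t2$spacing)
  expect_identical(make_skull_label(t2s, ph$brain)$data,
                   make_skull_label(ph$t2, ph$brain)$data)
  expect_identical(
    make_ventricle_mask(ph$tissue_ventricles, ph$majority_lv, t2s,
                        ph$periventricular)$data,
    make_ventricle_mask(ph$tissue_ventricles, ph$majority_lv, ph$t2,
                        ph$periventricular)$data)
  expect_identical(make_gm_mask(t2s, ph$tissue_gm)$data,
                   make_gm_mask(ph$t2, ph$tissue_gm)$data)
})
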