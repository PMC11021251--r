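test_that("radius map is r_near inside the dilated GM mask, r_far outside", {
  expect_error(build_radius_map(array(FALSE, c(4, 4, 4)), r_near = 1, r_far = 2),
               "r_near")
  d <- c(8, 8, 8)
  empty <- build_radius_map(array(FALSE, d))
  expect_true(all(empty$radius == empty$r_far))
  full <- build_radius_map(array(TRUE, d))
  expect_true(all(full$radius == full$r_near))

  gm <- array(FALSE, d); gm[1:4, , ] <- TRUE         # half space
  rm1 <- build_radius_map(gm, dilate_mm = 1)
  want <- oracle_dilate(gm, spherical_element(1, c(1, 1, 1))$offsets)
  expect_identical(rm1$near, want)
  expect_identical(rm1$radius == rm1$r_near, want)
})

test_that("patch similarity is Pearson correlation with a constant-patch 0", {
  a <- c(1, 2, 3, 7, 2)
  expect_equal(patch_similarity(a, a), 1)
  expect_equal(patch_similarity(a, -a), -1)
  expect_equal(patch_similarity(rep(4, 5), a), 0)
  expect_equal(patch_similarity(a, rep(0, 5)), 0)
  b <- c(2, 1, 5, 6, 3)
  expect_equal(patch_similarity(a, b), stats::cor(a, b))
  expect_error(patch_similarity(a, 1:4), "shapes")
})

test_that("identical atlases reproduce their labels exactly", {
  ph <- get_phantom(1, n = 48)
  atl <- list(list(intensity = ph$t2, labels = ph$labels),
              list(intensity = ph$t2, labels = ph$labels),
              list(intensity = ph$t2, labels = ph$labels))
  rm0 <- build_radius_map(neo_volume(ph$tissue_gm$data, ph$t2$spacing))
  fused <- fuse_labels(ph$t2, atl, radius_map = rm0)
  expect_identical(fused$labels$data, ph$labels$data)
  expect_true(all(fused$confidence$data >= 0 & fused$confidence$data <= 1))
})

test_that("weighted voting pools weights per label (2 moderate beat 1 perfect)", {
  # target patch at the centre of a 5^3 grid; atlases built so their best
  # (zero-offset) correlations are 0.9, 0.8 and 1.0
  d <- c(5, 5, 5)
  set.seed(11)
  t <- array(stats::rnorm(prod(d)), d)
  t <- t - mean(t)
  u <- array(stats::rnorm(prod(d)), d)
  u <- u - mean(u)
  u <- u - sum(u * t) / sum(t * t) * t      # orthogonal to t
  mix <- function(r) r * t / sqrt(sum(t^2)) + sqrt(1 - r^2) * u / sqrt(sum(u^2))
  atl <- list(
    list(intensity = neo_volume(mix(0.9)), labels = label_volume(array(7L, d))),
    list(intensity = neo_volume(mix(0.8)), labels = label_volume(array(7L, d))),
    list(intensity = neo_volume(t), labels = label_volume(array(9L, d))))
  rm0 <- build_radius_map(array(FALSE, d), r_near = 0.5, r_far = 0.5)
  fused <- fuse_labels(neo_volume(t), atl, patch_mm = 4, radius_map = rm0,
                       beta = 1)
  # w(7) = 0.9 + 0.8 = 1.7 > w(9) = 1.0
  expect_identical(fused$labels$data[3, 3, 3], 7L)
  expect_equal(fused$confidence$data[3, 3, 3], 1.7 / 2.7, tolerance = 0.02)
})

test_that("a shifted atlas is recovered by the offset search", {
  d <- c(14, 14, 14)
  set.seed(5)
  base <- smooth_gaussian(neo_volume(array(stats::rnorm(prod(d), 50, 30), d)), 1.5)
  lab <- array(0L, d)
  lab[base$data > stats::quantile(base$data, 0.6)] <- 4L
  lab[base$data < stats::quantile(base$data, 0.3)] <- 2L
  shift_int <- array(0, d)
  shift_int[1:(d[1] - 1), , ] <- base$data[2:d[1], , ]   # atlas shifted by -1 in x
  shift_lab <- array(0L, d)
  shift_lab[1:(d[1] - 1), , ] <- lab[2:d[1], , ]
  atl <- list(list(intensity = neo_volume(shift_int),
                   labels = label_volume(shift_lab)))
  rm1 <- build_radius_map(array(TRUE, d), r_near = 1, r_far = 1)
  fused <- fuse_labels(base, atl, patch_mm = 1, radius_map = rm1)
  interior <- fused$labels$data[3:11, 3:11, 3:11]
  expect_gt(mean(interior == lab[3:11, 3:11, 3:11]), 0.98)
})

test_that("fusion is invariant to atlas order and doubled by duplication", {
  ph <- get_phantom(2, n = 48)
  atl <- make_atlas_set(ph, n = 3, warp_mm = 1, noise_sd = 5, seed = 7)
  rmap <- build_radius_map(neo_volume(ph$tissue_gm$data, ph$t2$spacing))
  f1 <- fuse_labels(ph$t2, atl, radius_map = rmap)
  f2 <- fuse_labels(ph$t2, rev(atl), radius_map = rmap)
  expect_identical(f1$labels$data, f2$labels$data)

  # duplicating an atlas doubles its vote: 2 copies of A outvote one B
  d <- c(5, 5, 5)
  set.seed(3)
  t <- array(stats::rnorm(prod(d)), d)
  atlA <- list(intensity = neo_volume(t + stats::rnorm(prod(d), 0, 0.4)),
               labels = label_volume(array(7L, d)))
  atlB <- list(intensity = neo_volume(t),
               labels = label_volume(array(9L, d)))
  rm0 <- build_radius_map(array(FALSE, d), r_near = 0.5, r_far = 0.5)
  single <- fuse_labels(neo_volume(t), list(atlA, atlB), patch_mm = 4,
                        radius_map = rm0, beta = 1)
  doubled <- fuse_labels(neo_volume(t), list(atlA, atlA, atlB), patch_mm = 4,
                         radius_map = rm0, beta = 1)
  expect_identical(single$labels$data[3, 3, 3], 9L)   # perfect match wins
  expect_identical(doubled$labels$data[3, 3, 3], 7L)  # duplicated vote wins

  expect_error(fuse_labels(ph$t2, list()), "empty")
})

test_that("fusion matches the naive patch-voting oracle on small grids", {
  for (seed in 1:3) {
    d <- c(7, 6, 6)
    set.seed(seed)
    t <- array(stats::rnorm(prod(d), 50, 20), d)
    atl <- lapply(1:2, function(a) {
      list(intensity = neo_volume(t + array(stats::rnorm(prod(d), 0, 8), d)),
           labels = label_volume(array(sample(c(0L, 2L, 5L), prod(d), TRUE), d)))
    })
    el <- spherical_element(1, c(1, 1, 1))
    rm1 <- build_radius_map(array(TRUE, d), r_near = 1, r_far = 1)
    fused <- fuse_labels(neo_volume(t), atl, patch_mm = 1, radius_map = rm1,
                         beta = 2)
    ref <- oracle_fuse(t, lapply(atl, function(a) a$intensity$data),
                       lapply(atl, function(a) a$labels$data),
                       patch_offsets(1, c(1, 1, 1)), el$offsets, beta = 2)
    expect_identical(fused$labels$data, ref)
  }
})
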