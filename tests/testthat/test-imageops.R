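test_that("spherical elements enumerate exactly the in-radius offsets", {
  expect_error(spherical_element(0), "positive")
  expect_error(spherical_element(2, c(1, 0, 1)), "positive")

  e <- spherical_element(0.5, c(1, 1, 1))
  expect_identical(e$offsets, matrix(0L, 1, 3))

  e1 <- spherical_element(1, c(1, 1, 1))
  expect_equal(nrow(e1$offsets), 7)          # 6-neighbourhood cross
  expect_true(all(rowSums(abs(e1$offsets)) <= 1))

  # brute-force enumeration at anisotropy-free neonatal spacing
  sp <- c(0.63, 0.63, 0.63)
  e4 <- spherical_element(4, sp)
  g <- as.matrix(expand.grid(-6:6, -6:6, -6:6))
  nref <- sum(sqrt((g[, 1] * sp[1])^2 + (g[, 2] * sp[2])^2 +
                   (g[, 3] * sp[3])^2) <= 4)
  expect_equal(nrow(e4$offsets), nref)

  # symmetry and origin membership, anisotropic case
  ea <- spherical_element(2.2, c(0.5, 1, 2))
  expect_true(any(rowSums(abs(ea$offsets)) == 0))
  key <- paste(ea$offsets[, 1], ea$offsets[, 2], ea$offsets[, 3])
  neg <- paste(-ea$offsets[, 1], -ea$offsets[, 2], -ea$offsets[, 3])
  expect_setequal(key, neg)

  # offset count monotone in radius
  counts <- vapply(seq(0.5, 5, by = 0.5),
                   function(r) nrow(spherical_element(r, sp)$offsets), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("morphology matches Minkowski oracles and order relations", {
  el <- spherical_element(1.5, c(1, 1, 1))
  for (seed in 1:12) {
    m <- rand_mask(c(7, 8, 6), p = 0.25, seed = seed)
    expect_identical(binary_dilate(m, el) != 0, oracle_dilate(m, el$offsets))
    expect_identical(binary_erode(m, el) != 0, oracle_erode(m, el$offsets))
    op <- binary_opening(m, el) != 0
    cl <- binary_closing(m, el) != 0
    expect_true(all(op <= m))           # opening anti-extensive
    expect_true(all(m <= cl))           # closing extensive
  }

  # closing bridges a 1-voxel gap
  m <- array(FALSE, c(9, 5, 5))
  m[2:4, 2:4, 2:4] <- TRUE
  m[6:8, 2:4, 2:4] <- TRUE
  cl <- binary_closing(m, spherical_element(1, c(1, 1, 1)))
  expect_true(cl[5, 3, 3])                 # gap interior filled
  expect_equal(length(connected_components(cl, 6)$sizes), 1)  # blocks joined

  # opening removes an isolated voxel, keeps a large solid ball interior
  m2 <- array(FALSE, c(11, 11, 11))
  m2[6, 6, 6] <- TRUE
  expect_false(any(binary_opening(m2, spherical_element(2, c(1, 1, 1)))))
  ball <- array(FALSE, c(13, 13, 13))
  ai <- arrayInd(seq_len(13^3), rep(13L, 3))
  ball[sqrt(rowSums((ai - 7)^2)) <= 5] <- TRUE
  opb <- binary_opening(ball, spherical_element(2, c(1, 1, 1)))
  expect_true(opb[7, 7, 7])
  expect_true(all(opb <= ball))
})

test_that("connected components and largest component follow scan order", {
  expect_equal(length(connected_components(array(FALSE, c(4, 4, 4)))$sizes), 0)

  m <- array(FALSE, c(10, 6, 6))
  m[2:3, 2:3, 2:3] <- TRUE           # 8 voxels
  m[6:8, 2:4, 2:4] <- TRUE           # 27 voxels
  cc <- connected_components(m, 26)
  expect_setequal(unname(cc$sizes), c(8, 27))

  # corner contact: one component under 26, two under 6
  m2 <- array(FALSE, c(6, 6, 6))
  m2[2:3, 2:3, 2:3] <- TRUE
  m2[4:5, 4:5, 4:5] <- TRUE
  expect_equal(length(connected_components(m2, 26)$sizes), 1)
  expect_equal(length(connected_components(m2, 6)$sizes), 2)

  for (seed in 1:8) for (conn in c(6, 26)) {
    m3 <- rand_mask(c(6, 7, 5), p = 0.3, seed = seed)
    got <- connected_components(m3, conn)$labels
    ref <- oracle_components(m3, conn)
    expect_identical(got, ref)
  }

  # largest-component tie-break: first component in voxel scan order wins
  m4 <- array(FALSE, c(8, 4, 4))
  m4[6:7, 2:3, 2] <- TRUE            # later in scan order (larger k first?)
  m4[1:2, 1:2, 1] <- TRUE            # first voxel in scan order
  lc <- largest_component(m4, 26)
  expect_true(all(lc[1:2, 1:2, 1]))
  expect_false(any(lc[6:7, 2:3, 2]))

  single <- rand_mask(c(5, 5, 5), 0.9, seed = 3)
  single <- connected_components(single)$labels == 1
  expect_identical(largest_component(single) != 0, single)
})

test_that("distance transforms agree with exhaustive minima", {
  m <- array(FALSE, c(6, 6, 6))
  m[3, 3, 3] <- TRUE
  cb <- chessboard_distance(m)
  expect_equal(cb[4, 4, 4], 1)                  # diagonal neighbour
  expect_equal(cb[6, 5, 4], 3)                  # offset (3,2,1) -> max = 3
  ed <- euclidean_distance(m, c(0.63, 0.63, 0.63))
  expect_equal(ed[3, 3, 3], 0)
  expect_equal(ed[5, 3, 3], 1.26, tolerance = 1e-9)

  for (seed in 1:10) {
    dims <- c(8, 7, 9)
    mm <- rand_mask(dims, p = 0.05, seed = seed)
    if (!any(mm)) next
    expect_identical(chessboard_distance(mm), oracle_chessboard(mm))
    sp <- c(0.8, 1, 1.3)
    expect_equal(euclidean_distance(mm, sp), oracle_euclid(mm, sp),
                 tolerance = 1e-9)
  }
})

test_that("derivative filters follow the dark/bright sign convention", {
  const <- neo_volume(array(5, c(9, 9, 9)))
  expect_true(all(directional_second_derivative(const, 1)$data == 0))
  expect_true(all(abs(laplacian_of_gaussian(const, 1)$data) < 1e-9))

  # dark plane in a bright volume -> positive response on the plane
  dark <- array(100, c(11, 11, 11)); dark[6, , ] <- 20
  vd <- neo_volume(dark)
  expect_true(all(directional_second_derivative(vd, 1)$data[6, 3:9, 3:9] > 0))
  bright <- array(20, c(11, 11, 11)); bright[6, , ] <- 100
  vb <- neo_volume(bright)
  expect_true(all(directional_second_derivative(vb, 1)$data[6, 3:9, 3:9] < 0))

  # inversion antisymmetry at voxels with non-negligible gradient
  set.seed(7)
  v <- neo_volume(array(stats::rnorm(10^3, 50, 20), c(10, 10, 10)))
  d1 <- directional_second_derivative(v, 1)$data
  vneg <- neo_volume(max(v$data) - v$data)
  d2 <- directional_second_derivative(vneg, 1)$data
  g <- image_gradient(v, 1)$gmag$data
  sel <- g > 0.05 * max(g)
  expect_equal(d1[sel], -d2[sel], tolerance = 1e-6)

  # LoG: dark voxel positive, bright voxel negative
  dv <- array(100, c(9, 9, 9)); dv[5, 5, 5] <- 10
  expect_gt(laplacian_of_gaussian(neo_volume(dv), 1)$data[5, 5, 5], 0)
  bv <- array(10, c(9, 9, 9)); bv[5, 5, 5] <- 100
  expect_lt(laplacian_of_gaussian(neo_volume(bv), 1)$data[5, 5, 5], 0)
})

test_that("intensity k-means orders classes dark to bright and is stable", {
  set.seed(1)
  modes <- c(10, 40, 70, 100)
  vals <- unlist(lapply(modes, function(m) stats::rnorm(200, m, 1.5)))
  cls <- kmeans_intensity(vals, 4)
  truth <- rep(0:3, each = 200)
  expect_identical(cls, truth)

  # threshold-midpoint oracle: class boundaries between well-separated modes
  mids <- (modes[-1] + modes[-4]) / 2
  oracle <- findInterval(vals, mids)
  expect_identical(cls, oracle)

  expect_identical(kmeans_intensity(c(3, 9), 2), c(0L, 1L))
  expect_error(kmeans_intensity(rep(5, 10), 2), "degenerate")

  # order invariance and shift equivariance
  perm <- sample(length(vals))
  expect_identical(kmeans_intensity(vals[perm], 4), cls[perm])
  expect_identical(kmeans_intensity(vals + 123.4, 4), cls)
})

test_that("convex hull mask fills cavities and is exact on small grids", {
  expect_false(any(convex_hull_mask(array(FALSE, c(4, 4, 4)))))

  # solid ball: unchanged up to the boundary shell
  d <- c(13, 13, 13)
  ai <- arrayInd(seq_len(prod(d)), d)
  ball <- array(sqrt(rowSums((ai - 7)^2)) <= 4.5, d)
  hull <- convex_hull_mask(ball)
  expect_true(all(ball <= hull))
  expect_lt(sum(hull & !ball), 30)   # only discretisation slack at the shell

  # C-shape: cavity voxels included; exact against the half-space oracle
  m <- array(FALSE, c(7, 7, 4))
  m[2:6, 2:3, 2:3] <- TRUE
  m[2:3, 2:6, 2:3] <- TRUE
  m[2:6, 5:6, 2:3] <- TRUE
  hull <- convex_hull_mask(m)
  expect_true(all(hull[4:5, 4, 2:3]))     # the cavity
  expect_identical(hull, oracle_hull_mask(m))
})

test_that("Canny edge mask finds planar steps and respects thresholds", {
  const <- neo_volume(array(3, c(8, 8, 8)))
  expect_false(any(edge_mask(const)$data))

  step <- array(10, c(12, 10, 10)); step[7:12, , ] <- 110
  vs <- neo_volume(step)
  em <- edge_mask(vs, sigma_mm = 1)$data
  expect_true(any(em))
  idx <- which(em, arr.ind = TRUE)
  expect_true(all(idx[, 1] %in% 5:8))      # edge voxels hug the step plane

  # step weaker than the low threshold -> empty
  em2 <- edge_mask(vs, low = 1e6, high = 2e6, sigma_mm = 1)$data
  expect_false(any(em2))
})
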