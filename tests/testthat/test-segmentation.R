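test_that("spatial features of a constant frame are flat", {
  sf <- compute_spatial_features(matrix(0.5, 24, 24), window = 9)
  expect_equal(range(sf[, , "mean"]), c(0.5, 0.5))
  expect_equal(max(sf[, , "sd"]), 0)
  expect_equal(max(sf[, , "entropy"]), 0)
})

test_that("spatial features of a checkerboard match direct enumeration", {
  frame <- outer(1:30, 1:30, function(i, j) (i + j) %% 2)
  sf <- compute_spatial_features(frame, window = 9)
  # interior 9x9 window holds 41 pixels of the center's parity and 40 of
  # the other, so the mean is (40 + center value) / 81
  for (px in list(c(10, 10), c(15, 16), c(20, 13))) {
    expect_equal(unname(sf[px[1], px[2], "mean"]),
                 (40 + frame[px[1], px[2]]) / 81, tolerance = 1e-12)
    expect_equal(unname(sf[px[1], px[2], "entropy"]), 1, tolerance = 1e-3)
  }
})

test_that("an isolated bright pixel only perturbs covering windows", {
  frame <- matrix(0, 25, 25)
  frame[13, 13] <- 1
  sf <- compute_spatial_features(frame, window = 9)
  sdv <- sf[, , "sd"]
  covered <- outer(1:25, 1:25,
                   function(i, j) abs(i - 13) <= 4 & abs(j - 13) <= 4)
  expect_true(all(sdv[covered] > 0))
  expect_true(all(sdv[!covered] == 0))
})

test_that("spatial features reject invalid input", {
  expect_error(compute_spatial_features(matrix(0.5, 10, 10), window = 8),
               "odd")
  expect_error(compute_spatial_features(matrix(0.5, 4, 4), window = 9),
               "too large")
  expect_error(compute_spatial_features(matrix(2, 10, 10), window = 3),
               "\\[0, 1\\]")
})

test_that("the mean channel is linear in global intensity scaling", {
  set.seed(42)
  frame <- matrix(runif(400), 20, 20)
  m1 <- compute_spatial_features(frame, 5)[, , "mean"]
  m2 <- compute_spatial_features(frame / 2, 5)[, , "mean"]
  expect_equal(m2, m1 / 2, tolerance = 1e-12)
})

test_that("temporal std matches hand-computed cases", {
  static <- array(0.3, dim = c(4, 4, 10))
  expect_equal(max(compute_temporal_std(static)), 0)
  alt <- array(rep(c(0, 1), each = 4), dim = c(2, 2, 10))
  expect_equal(compute_temporal_std(alt)[1, 1], 0.5)
  three <- array(rep(c(0, 0.5, 1), each = 4), dim = c(2, 2, 3))
  expect_equal(compute_temporal_std(three)[2, 2], sqrt(1 / 6),
               tolerance = 1e-12)
  expect_error(compute_temporal_std(array(0, c(2, 2, 1))), "2 frames")
})

test_that("kmeans_segment recovers well-separated blobs exactly", {
  skip_if_not_installed("mclust")
  set.seed(1)
  n <- 120
  centers <- matrix(c(0, 0, 20, 0, 0, 20), 3, 2, byrow = TRUE)
  truth <- rep(1:3, each = n)
  X <- centers[truth, ] + matrix(rnorm(2 * 3 * n, sd = 0.5), 3 * n, 2)
  feats <- array(X, dim = c(3 * n, 1, 2))
  labels <- kmeans_segment(feats, k = 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(as.vector(labels), truth), 1)
})

test_that("kmeans_segment is deterministic and validates inputs", {
  set.seed(2)
  feats <- array(runif(600), dim = c(20, 10, 3))
  l1 <- kmeans_segment(feats, k = 3, seed = 5)
  l2 <- kmeans_segment(feats, k = 3, seed = 5)
  expect_identical(l1, l2)
  expect_true(all(kmeans_segment(feats, k = 1) == 1L))
  same <- array(1, dim = c(4, 4, 2))
  expect_error(kmeans_segment(same, k = 2), "distinct")
})

test_that("kmeans partition is invariant to per-channel affine rescaling", {
  set.seed(3)
  base <- matrix(rnorm(300), 150, 2)
  base[1:50, 1] <- base[1:50, 1] + 15
  base[51:100, 2] <- base[51:100, 2] + 15
  f1 <- array(base, dim = c(150, 1, 2))
  scaled <- sweep(sweep(base, 2, c(3, 0.1), "*"), 2, c(-7, 100), "+")
  f2 <- array(scaled, dim = c(150, 1, 2))
  l1 <- as.vector(kmeans_segment(f1, k = 3, seed = 9))
  l2 <- as.vector(kmeans_segment(f2, k = 3, seed = 9))
  # identical partitions up to label permutation
  tab <- table(l1, l2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("select_wall picks the dynamic cluster among visible ones", {
  labels <- matrix(1L, 20, 20)
  labels[, 11:15] <- 2L   # bright & moving
  labels[, 16:20] <- 3L   # brighter but static
  tstd <- matrix(0, 20, 20); tstd[, 11:15] <- 0.2
  inten <- matrix(0.1, 20, 20)
  inten[, 11:15] <- 0.7; inten[, 16:20] <- 0.9
  mask <- select_wall(labels, tstd, inten)
  expect_true(all(mask[, 11:15]))
  expect_true(!any(mask[, c(1:10, 16:20)]))
})

test_that("select_wall raises classed errors on degenerate scenes", {
  labels <- matrix(rep(1:2, each = 200), 20, 20)
  tstd <- matrix(0, 20, 20)
  inten <- matrix(rep(c(0.2, 0.8), each = 200), 20, 20)
  expect_error(select_wall(labels, tstd, inten), class = "cartwave_no_wall")
  # all clusters at/below the global intensity median
  expect_error(select_wall(matrix(1L, 5, 5), matrix(1, 5, 5),
                           matrix(0.5, 5, 5)),
               class = "cartwave_no_wall")
})

test_that("segment_wall recovers the phantom wall band", {
  ph <- generate_phantom(phantom_config("young", seed = 1))
  seg <- segment_wall(ph$sequence, seed = 1)
  expect_gte(dice_coefficient(seg$wall_mask, ph$truth$wall_mask), 0.8)
  # the wall mask is a single 4-connected component
  comp <- cartwave:::label_components4(seg$wall_mask)
  expect_equal(length(setdiff(unique(as.vector(comp)), 0L)), 1L)
  # lumen / wall / tissue sort into predominantly distinct clusters
  cfg <- ph$config
  lumen_rows <- 1:(cfg$wall_row - 10)
  tissue_rows <- (cfg$wall_row + cfg$wall_thickness + 10):cfg$height
  purity <- function(region_mask) {
    max(table(seg$labels[region_mask])) / sum(region_mask)
  }
  lum <- matrix(FALSE, cfg$height, cfg$width); lum[lumen_rows, ] <- TRUE
  tis <- matrix(FALSE, cfg$height, cfg$width); tis[tissue_rows, ] <- TRUE
  expect_gte(purity(lum), 0.9)
  expect_gte(purity(tis), 0.9)
  expect_gte(purity(ph$truth$wall_mask), 0.9)
})

test_that("a static sequence yields a no-wall-found error", {
  ph <- generate_phantom(phantom_config("young", amplitude = 0,
                                        speckle_scale = 0, seed = 1))
  expect_error(segment_wall(ph$sequence, seed = 1),
               class = "cartwave_no_wall")
})
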