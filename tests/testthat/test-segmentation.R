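# Segmentation on constructed fixtures (airway/lung growing, splitting,
# hole filling). Phantom-scale checks live in the acceptance suite.

make_two_ellipsoid_volume <- function(bridge = FALSE) {
  d <- c(40, 40, 60)
  g <- index_grids_list(d)
  vol <- array(40, d)
  e1 <- ((g$i - 20) / 14)^2 + ((g$j - 20) / 12)^2 + ((g$k - 16) / 9)^2 <= 1
  e2 <- ((g$i - 20) / 14)^2 + ((g$j - 20) / 12)^2 + ((g$k - 45) / 9)^2 <= 1
  vol[e1 | e2] <- -850
  mask <- e1 | e2
  if (bridge) {
    vol[20, 20:21, 25:36] <- -850
    mask[20, 20:21, 25:36] <- TRUE
  }
  list(vol = volume3d(vol, c(1, 1, 1)), mask = array(mask, d))
}

test_that("airway growing requires an air-dense seed and is deterministic", {
  p <- phantom_pipeline()
  vol <- p$pair$insp
  seed <- find_trachea_seed(vol)
  expect_lt(vol$values[seed[1], seed[2], seed[3]], -950)
  aw1 <- segment_airway(vol, seed)
  aw2 <- segment_airway(vol, seed)
  expect_identical(aw1, aw2)
  # seed in soft tissue (torso center column, outside the lungs) errors
  soft <- c(5, 48, 48)
  expect_gt(vol$values[soft[1], soft[2], soft[3]], -300)
  expect_error(segment_airway(vol, soft), "seed error")
})

test_that("airway mask recovers the phantom's airway tube", {
  p <- phantom_pipeline()
  vol <- p$pair$insp
  aw <- segment_airway(vol, find_trachea_seed(vol))
  d <- dim(vol$values)
  g <- index_grids_list(d)
  pts <- cbind(as.numeric(g$i) - 1, as.numeric(g$j) - 1, as.numeric(g$k) - 1)
  tube <- bprm:::airway_distance(pts, p$truth$geometry) <= 0
  expect_gt(sum(aw & array(tube, d)) / sum(tube), 0.95)
})

test_that("lung growing under an impossible bound returns an empty, leak-free mask", {
  p <- phantom_pipeline()
  vol <- p$pair$insp
  aw <- segment_airway(vol, find_trachea_seed(vol))
  empty <- segment_lungs(vol, aw, upper_bound_hu = -1100)
  expect_equal(sum(empty), 0)
})

test_that("morphological closing fills a small vessel hole only at sufficient radius", {
  d <- c(24, 24, 24)
  g <- index_grids_list(d)
  vol <- array(40, d)
  lung <- (g$i - 12)^2 + (g$j - 12)^2 + (g$k - 12)^2 <= 81
  vol[lung] <- -850
  vol[12, 12, 11:13] <- 30 # 3-voxel vessel
  # seed the growth through a synthetic "airway" voxel next to the lung
  airway <- array(FALSE, d)
  airway[12, 12, 4] <- TRUE
  vol[12, 12, 4] <- -1000
  v <- volume3d(vol, c(1, 1, 1))
  no_close <- segment_lungs(v, airway, closing_iter = 0)
  with_close <- segment_lungs(v, airway, closing_iter = 2)
  expect_false(any(no_close[12, 12, 11:13]))
  expect_true(all(with_close[12, 12, 11:13]))
})

test_that("disjoint lungs split with zero erosion and every voxel is labeled", {
  fix <- make_two_ellipsoid_volume(bridge = FALSE)
  side <- split_left_right(fix$mask)
  expect_equal(attr(side, "erosions"), 0)
  expect_true(all(side[fix$mask] > 0))
  expect_setequal(unique(as.integer(side[fix$mask])), c(1L, 2L))
  # left = larger x centroid
  g <- index_grids_list(dim(fix$mask))
  expect_gt(mean(g$k[side == 1L]), mean(g$k[side == 2L]))
})

test_that("a thin bridge is cut by erosion and both halves keep their voxels", {
  fix <- make_two_ellipsoid_volume(bridge = TRUE)
  expect_equal(max(bprm:::label_components(fix$mask)), 1)
  side <- split_left_right(fix$mask)
  expect_gte(attr(side, "erosions"), 1)
  expect_true(all(side[fix$mask] > 0))
  g <- index_grids_list(dim(fix$mask))
  # each ellipsoid body ends up in one side
  expect_true(all(side[fix$mask & g$k <= 20] == 2L))
  expect_true(all(side[fix$mask & g$k >= 41] == 1L))
})

test_that("a single sphere cannot be split", {
  d <- c(24, 24, 24)
  g <- index_grids_list(d)
  sph <- array((g$i - 12)^2 + (g$j - 12)^2 + (g$k - 12)^2 <= 64, d)
  expect_error(split_left_right(sph), "split error")
})

test_that("side and group labels partition the lung mask", {
  p <- phantom_pipeline()
  r <- p$regions_i
  lung <- r$side > 0L
  expect_true(all(r$group[lung] %in% c(1L, 2L)))
  expect_true(all(r$group[!lung] == 0L))
  expect_equal(sum(parenchyma_mask(r)), sum(lung) - sum(r$airway & lung))
})
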