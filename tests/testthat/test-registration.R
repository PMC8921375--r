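# Point sampling, CPD and landmark warping on constructed cases; the 96^3
# phantom recovery check lives in the acceptance suite.

test_that("interior grid sampling of a cube follows grid arithmetic", {
  d <- c(30, 30, 30)
  mask <- array(FALSE, d)
  mask[1:20, 1:20, 1:20] <- TRUE  # 20 mm cube anchored at the origin
  geom <- make_geometry(d)
  ps <- sample_points(mask, geom, target_spacing = 5, role = "interior")
  expect_equal(nrow(ps$coords), 64) # 4 x 4 x 4 bins
  ps2 <- sample_points(mask, geom, target_spacing = 5, role = "interior")
  expect_identical(ps$coords, ps2$coords)
})

test_that("sampling never returns an empty set and validates the pitch", {
  d <- c(12, 12, 12)
  mask <- array(FALSE, d)
  mask[4:6, 4:6, 4:6] <- TRUE
  geom <- make_geometry(d)
  ps <- sample_points(mask, geom, target_spacing = 50)
  expect_gte(nrow(ps$coords), 1)
  expect_error(sample_points(mask, geom, target_spacing = 0.5),
               "parameter error")
})

test_that("surface sampling stays on the mask boundary", {
  d <- c(24, 24, 24)
  g <- index_grids_list(d)
  mask <- array((g$i - 12)^2 + (g$j - 12)^2 + (g$k - 12)^2 <= 81, d)
  geom <- make_geometry(d)
  ps <- sample_points(mask, geom, target_spacing = 4, role = "surface")
  shell <- mask & !bprm:::erode_mask(mask, 1)
  vox <- round(ps$coords) + 1
  expect_true(all(shell[vox]))
})

test_that("CPD is the identity on identical sets and recovers a rigid shift", {
  set.seed(2)
  Y <- as.matrix(expand.grid(seq(0, 40, 10), seq(0, 40, 10), seq(0, 40, 10))) +
    matrix(runif(375, -2, 2), 125, 3)
  fit <- cpd_nonrigid(Y, Y)
  expect_lt(max(abs(fit$moved_points - Y)), 1e-6)
  X <- sweep(Y, 2, c(5, 0, 0), `+`)
  fit2 <- cpd_nonrigid(Y, X, beta = 30)
  expect_lt(mean(sqrt(rowSums((fit2$moved_points - X)^2))), 0.1)
})

test_that("the CPD mixture variance is non-increasing across EM iterations", {
  set.seed(4)
  Y <- matrix(runif(240, 0, 50), 80, 3)
  X <- Y + cbind(2 * sin(Y[, 1] / 10), -1.5 * cos(Y[, 2] / 12), 0.05 * Y[, 3])
  fit <- cpd_nonrigid(Y, X, beta = 20)
  expect_true(all(diff(fit$sigma2_trace) <= 1e-9))
})

test_that("cpd_transform moves unseen points consistently with the fit", {
  set.seed(5)
  Y <- matrix(runif(150, 0, 40), 50, 3)
  X <- sweep(Y, 2, c(3, -2, 1), `+`)
  fit <- cpd_nonrigid(Y, X, beta = 40)
  Z <- matrix(runif(30, 5, 35), 10, 3)
  moved <- cpd_transform(fit, Z)
  expect_equal(moved, sweep(Z, 2, c(3, -2, 1), `+`), tolerance = 0.2)
})

test_that("warping with identical landmarks is an identity resample", {
  d <- c(20, 20, 20)
  g <- index_grids_list(d)
  vals <- array(-800 + 3 * g$i + 2 * g$j - g$k, d)
  vol <- volume3d(vals, c(1, 1, 1), phase = "expiratory")
  set.seed(6)
  lm <- matrix(runif(45, 2, 17), 15, 3)
  out <- warp_volume(vol, lm, lm, vol)
  expect_equal(out$values, vals, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("landmarks encoding a uniform shift reproduce the shifted image", {
  d <- c(24, 24, 24)
  g <- index_grids_list(d)
  # smooth HU field
  vals <- array(-800 + 40 * sin(g$i / 5) + 30 * cos(g$j / 6) + 2 * g$k, d)
  vol <- volume3d(vals, c(1, 1, 1), phase = "expiratory")
  set.seed(7)
  src <- matrix(runif(60, 6, 18), 20, 3)
  dst <- sweep(src, 2, c(4, 0, 0), `-`) # content moved -4 mm in z
  out <- warp_volume(vol, src, dst, vol)
  # voxel (i,j,k) of the output should equal input at (i+4, j, k)
  inner <- 2:18
  diff_hu <- out$values[inner, inner, inner] - vals[inner + 4, inner, inner]
  expect_lt(max(abs(diff_hu)), 1)
})

test_that("coplanar landmarks raise a degenerate-geometry error", {
  d <- c(10, 10, 10)
  vol <- make_geometry(d)
  lm <- cbind(5, runif(10, 1, 8), runif(10, 1, 8))
  expect_error(warp_volume(vol, lm, lm, vol), "degenerate")
})

test_that("registration halves the HU mismatch attainable by the true field", {
  p <- phantom_pipeline()
  pair <- p$pair
  truth <- p$truth
  d <- dim(pair$insp$values)
  g <- index_grids_list(d)
  pts <- cbind(as.numeric(g$i) - 1, as.numeric(g$j) - 1, as.numeric(g$k) - 1)
  cls <- bprm:::phantom_membership(pts, truth$geometry,
                                   as.data.frame(truth$bulla_catalog))
  pure <- array(cls == "parenchyma", d) & parenchyma_mask(p$regions_i)
  # oracle: resample through the true deformation
  def <- phantom_deform(truth, pts)
  idx <- sweep(def, 2, pair$exp$spacing, `/`) + 1
  perfect <- array(bprm:::sample_trilinear(pair$exp$values, idx), d)
  sel0 <- pure & !is.na(perfect)
  mad_oracle <- mean(abs(perfect[sel0] - pair$insp$values[sel0]))
  mad_un <- mean(abs(pair$exp$values[pure] - pair$insp$values[pure]))
  sel <- pure & attr(p$reg$coreg, "valid")
  mad_reg <- mean(abs(p$reg$coreg$values[sel] - pair$insp$values[sel]))
  red <- 1 - mad_reg / mad_un
  red_oracle <- 1 - mad_oracle / mad_un
  expect_gt(red, 0.35)             # absolute improvement
  expect_gt(red / red_oracle, 0.6) # >= 60% of what the true field achieves
})
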