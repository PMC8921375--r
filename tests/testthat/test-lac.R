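# Low attenuation cluster extraction: erosion depth, core splitting,
# predominance classification, region assignment.

test_that("erosion depth matches morphology arithmetic on simple solids", {
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(erosion_depth_map(single)[3, 3, 3], 0L)
  cube <- array(TRUE, c(5, 5, 5))
  dm <- erosion_depth_map(cube)
  expect_equal(dm[3, 3, 3], 2L)
  expect_true(all(dm[1, , ] == 0L))
})

test_that("erosion depth equals the brute-force repeated-erosion oracle", {
  for (s in 1:3) {
    m <- random_lesion_mask(seed = s)
    expect_identical(erosion_depth_map(m), brute_force_depth(m))
  }
})

test_that("disjoint components become separate clusters with exact voxel counts", {
  d <- c(20, 20, 40)
  les <- array(FALSE, d)
  les[7:13, 7:13, 5:11] <- TRUE
  les[9:11, 9:11, 30:32] <- TRUE
  lacs <- extract_lacs(les)
  expect_equal(nrow(lacs), 2)
  expect_setequal(lacs$voxel_count, c(343L, 27L))
  expect_equal(sum(lacs$voxel_count), sum(les))
})

test_that("a dumbbell splits into two clusters, one cube each", {
  d <- c(30, 15, 15)
  db <- array(FALSE, d)
  db[2:10, 3:11, 3:11] <- TRUE
  db[16:24, 3:11, 3:11] <- TRUE
  db[11:15, 7, 7] <- TRUE
  lacs <- extract_lacs(db)
  expect_equal(nrow(lacs), 2)
  labels <- attr(lacs, "labels")
  expect_equal(length(unique(labels[db])), 2)
  # each 9^3 cube is entirely within one cluster
  expect_equal(length(unique(as.integer(labels[2:10, 3:11, 3:11]))), 1)
  expect_equal(length(unique(as.integer(labels[16:24, 3:11, 3:11]))), 1)
  expect_true(labels[5, 7, 7] != labels[20, 7, 7])
  expect_equal(sum(lacs$voxel_count), sum(db))
})

test_that("min_core_depth = Inf degenerates to plain connected components", {
  for (s in 1:5) {
    m <- random_lesion_mask(seed = 10 + s)
    lacs <- extract_lacs(m, min_core_depth = Inf)
    cc <- bprm:::label_components(m, 26)
    expect_equal(nrow(lacs), max(cc))
    expect_equal(sort(lacs$voxel_count), sort(tabulate(cc[cc > 0])))
  }
})

test_that("splitting partitions the mask and LADs sum exactly to LAV/100", {
  for (s in 1:5) {
    m <- random_lesion_mask(seed = 20 + s)
    n_par <- 5000
    lacs <- extract_lacs(m, parenchyma_count = n_par)
    labels <- attr(lacs, "labels")
    expect_true(all(labels[m] > 0L))
    expect_true(all(labels[!m] == 0L))
    expect_equal(sum(lacs$voxel_count), sum(m))
    expect_equal(sum(lacs$lad), sum(m) / n_par, tolerance = 1e-14)
  }
})

test_that("re-extracting a single-core cluster returns it unchanged", {
  d <- c(20, 20, 20)
  g <- index_grids_list(d)
  blob <- array((g$i - 10)^2 + (g$j - 10)^2 + (g$k - 10)^2 <= 36, d)
  l1 <- extract_lacs(blob)
  expect_equal(nrow(l1), 1)
  l2 <- extract_lacs(attr(l1, "labels") == l1$id[1])
  expect_equal(nrow(l2), 1)
  expect_equal(l2$voxel_count, l1$voxel_count)
})

test_that("predominance classification follows the majority rule and fSAD accounting", {
  d <- c(10, 10, 30)
  lesion <- array(FALSE, d)
  lesion[3:7, 3:7, 2:6] <- TRUE    # cluster A
  lesion[3:7, 3:7, 20:24] <- TRUE  # cluster B
  lacs <- extract_lacs(lesion, phase = "expiratory", parenchyma_count = 1000)
  prm_cls <- array(0L, d)
  prm_cls[lesion] <- 3L                       # A: all emphysema
  prm_cls[3:7, 3:7, 20:24] <- 2L              # B: all fSAD
  # make cluster B 40% emphysema / 60% fSAD
  b_idx <- which(array(FALSE, d) | (function(x) {x[3:7,3:7,20:24] <- TRUE; x})(array(FALSE, d)))
  prm_cls[b_idx[1:50]] <- 3L
  prm <- structure(list(class = prm_cls, parenchyma = array(TRUE, d),
                        thresholds = thresholds()), class = "prm_map")
  out <- classify_lac_predominance(lacs, prm)
  a <- out[out$centroid_x < 10, ]
  b <- out[out$centroid_x > 10, ]
  expect_equal(a$lac_class, "emph_predominant")
  expect_equal(b$lac_class, "fsad")
  expect_equal(b$fsad_voxels, 75L) # 125 voxels, 50 emphysema, 75 fSAD
  expect_equal(b$lad_eff, 75 / 1000)
  # phase guard
  lacs_i <- extract_lacs(lesion, phase = "inspiratory")
  expect_error(classify_lac_predominance(lacs_i, prm), "phase error")
})

test_that("region assignment is by majority with ties toward lower", {
  d <- c(20, 10, 10)
  lesion <- array(FALSE, d)
  lesion[4:13, 4:6, 4:6] <- TRUE   # 10 z-slabs: will straddle the boundary
  lacs <- extract_lacs(lesion)
  regions <- region_mask(
    side = array(1L, d),
    group = array(rep(c(2L, 1L), times = c(8, 12)), d), # lower below z=9
    airway = array(FALSE, d)
  )
  # 5 slabs in lower (4:8), 5 in upper (9:13): exact tie -> lower
  out <- assign_regions(lacs, regions)
  expect_equal(out$group, "lower")
  # 60/40 in favour of upper
  lesion2 <- array(FALSE, d)
  lesion2[5:14, 4:6, 4:6] <- TRUE  # 4 lower, 6 upper
  out2 <- assign_regions(extract_lacs(lesion2), regions)
  expect_equal(out2$group, "upper")
  expect_equal(out2$side, "left")
})
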