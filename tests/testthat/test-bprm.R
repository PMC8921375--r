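# BPRM severity distribution and grid aggregation on constructed subjects.

# a hand-built "subject": two lesions in one lung, known model terms
bprm_fixture <- function(beta_upper = -0.8, beta_lower = -0.3) {
  d <- c(40, 20, 20)
  lesion <- array(FALSE, d)
  # each lesion sits entirely inside one 10 mm grid cell (mm coords 30-34, 2-6)
  lesion[31:35, 3:7, 3:7] <- TRUE  # upper lesion, 125 voxels
  lesion[3:7, 3:7, 3:7] <- TRUE    # lower lesion, 125 voxels
  regions <- region_mask(
    side = array(1L, d),
    group = array(rep(c(2L, 1L), times = c(20, 20)), d),
    airway = array(FALSE, d)
  )
  n_par <- prod(d)
  lacs <- extract_lacs(lesion, parenchyma_count = n_par,
                       geometry = make_geometry(d), phase = "inspiratory")
  lacs <- assign_regions(lacs, regions)
  # empty expiratory side
  lacs_exp <- extract_lacs(array(FALSE, d), parenchyma_count = n_par,
                           geometry = make_geometry(d), phase = "expiratory")
  lacs_exp <- classify_lac_predominance(
    lacs_exp,
    structure(list(class = array(0L, d), parenchyma = array(TRUE, d),
                   thresholds = thresholds()), class = "prm_map"))
  lacs_exp <- assign_regions(lacs_exp, regions)
  pool <- rlnorm(100, log(0.002), 1.2)
  scales <- list(emph950 = fit_scale_model(pool, 10, "inspiratory"),
                 fsad = fit_scale_model(pool, 10, "expiratory"))
  sc <- assign_scale(scales$emph950, 125 / n_par)
  terms <- tibble::tibble(
    term = sprintf(c("emph950_upper_s%02d", "emph950_lower_s%02d"), sc),
    type = "emph950", group = c("upper", "lower"), scale = sc,
    estimate = c(beta_upper, beta_lower), p_value = 0.001)
  model <- structure(list(intercept = 70, terms = terms, alpha = 0.05,
                          fit = NULL, response = "fev1_fvc"),
                     class = "airflow_model")
  prm <- structure(list(class = array(1L, d), parenchyma = array(TRUE, d),
                        thresholds = thresholds()), class = "prm_map")
  prm$class[lesion] <- 3L
  list(d = d, lesion = lesion, regions = regions, lacs = lacs,
       lacs_exp = lacs_exp, scales = scales, model = model, prm = prm,
       n_par = n_par, geometry = make_geometry(d))
}

test_that("voxel contributions reproduce beta * LAD% per cluster exactly", {
  set.seed(1)
  fx <- bprm_fixture()
  contrib <- voxel_contribution(fx$lacs, fx$lacs_exp, fx$prm, fx$model,
                                fx$scales, fx$n_par)
  expect_equal(sum(contrib == 0), prod(fx$d) - 250)
  lad_pct <- 100 * 125 / fx$n_par
  upper_sum <- sum(contrib[21:40, , ])
  lower_sum <- sum(contrib[1:20, , ])
  expect_equal(upper_sum, -0.8 * lad_pct, tolerance = 1e-12)
  expect_equal(lower_sum, -0.3 * lad_pct, tolerance = 1e-12)
  # per-voxel value is beta * 100 / parenchyma_count
  expect_equal(unique(contrib[contrib < -0.003]), -0.8 * 100 / fx$n_par)
  expect_equal(unique(contrib[contrib < 0 & contrib > -0.003]),
               -0.3 * 100 / fx$n_par)
})

test_that("the grid conserves the model prediction and ranks by severity", {
  set.seed(2)
  fx <- bprm_fixture()
  contrib <- voxel_contribution(fx$lacs, fx$lacs_exp, fx$prm, fx$model,
                                fx$scales, fx$n_par)
  grid <- aggregate_grid(contrib, fx$regions, fx$prm, fx$geometry, fx$model,
                         cell_size = 10)
  # conservation against the subject-level prediction
  recs <- lac_predictor_records(fx$lacs, fx$lacs_exp)
  pred <- predict(fx$model, assemble_predictors(recs, fx$scales))
  expect_equal(grid$whole_lung_prediction, pred, tolerance = 1e-9)
  # the high-|beta| (upper) lesion cell ranks most severe
  top <- grid$cells[grid$cells$rank == 1, ]
  expect_equal(top$group, "upper")
  expect_equal(top$severity, -0.8 * 100 * 125 / fx$n_par, tolerance = 1e-12)
  # grid refinement preserves the total and the most severe lesion
  grid2 <- aggregate_grid(contrib, fx$regions, fx$prm, fx$geometry, fx$model,
                          cell_size = 5)
  expect_equal(sum(grid2$cells$severity), sum(grid$cells$severity),
               tolerance = 1e-12)
  expect_equal(grid2$cells$group[grid2$cells$rank == 1], "upper")
})

test_that("a degenerate single-cell grid carries the whole deviation", {
  set.seed(3)
  fx <- bprm_fixture()
  contrib <- voxel_contribution(fx$lacs, fx$lacs_exp, fx$prm, fx$model,
                                fx$scales, fx$n_par)
  grid <- aggregate_grid(contrib, fx$regions, fx$prm, fx$geometry, fx$model,
                         cell_size = 100)
  expect_equal(nrow(grid$cells), 1)
  expect_equal(grid$cells$severity[1],
               grid$whole_lung_prediction - grid$intercept, tolerance = 1e-12)
})

test_that("an empty lesion set yields a uniform zero map and NIfTI round-trips", {
  set.seed(4)
  fx <- bprm_fixture()
  zero <- array(0, fx$d)
  grid <- aggregate_grid(zero, fx$regions, fx$prm, fx$geometry, fx$model,
                         cell_size = 10)
  expect_true(all(grid$cells$severity == 0))
  # round trip of a non-trivial severity map at float32 precision
  contrib <- voxel_contribution(fx$lacs, fx$lacs_exp, fx$prm, fx$model,
                                fx$scales, fx$n_par)
  grid2 <- aggregate_grid(contrib, fx$regions, fx$prm, fx$geometry, fx$model,
                          cell_size = 10)
  nii <- tempfile(fileext = ".nii.gz")
  csv <- tempfile(fileext = ".csv")
  export_bprm(grid2, fx$geometry, nii, csv)
  back <- read_volume(nii)
  cell_map <- attr(grid2, "cell_map")
  for (cl in c(1, which.max(grid2$cells$n_parenchyma))) {
    sel <- cell_map == grid2$cells$cell[cl]
    expect_equal(unique(round(back$values[sel], 5)),
                 round(grid2$cells$severity[cl], 5), tolerance = 1e-4)
  }
  tab <- read.csv(csv)
  expect_equal(nrow(tab), nrow(grid2$cells))
  expect_equal(tab$rank, sort(tab$rank))
})
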