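# Threshold rules, LAV accounting and PRM classification semantics.

tiny_pair <- function(insp_hu, exp_hu) {
  d <- c(4, 4, 4)
  insp <- volume3d(array(insp_hu, d), c(1, 1, 1))
  exp <- volume3d(array(exp_hu, d), c(1, 1, 1), phase = "expiratory")
  list(insp = insp, exp = exp, par = array(TRUE, d))
}

test_that("binarize uses strict inequality below the threshold", {
  d <- c(4, 4, 4)
  par <- array(TRUE, d)
  v <- volume3d(array(-1000, d), c(1, 1, 1))
  expect_true(all(binarize(v, par, -950)))
  v2 <- volume3d(array(-950, d), c(1, 1, 1))
  expect_false(any(binarize(v2, par, -950)))
})

test_that("LAV% is plain arithmetic over the parenchyma and errors when empty", {
  d <- c(4, 4, 4)
  par <- array(TRUE, d)
  lesion <- array(FALSE, d)
  lesion[1:16] <- TRUE
  expect_equal(lav_percent(lesion, par), 100 * 16 / 64)
  expect_equal(lav_percent(par, par), 100)
  expect_error(lav_percent(lesion, array(FALSE, d)), "division error")
})

test_that("LAV% is monotonically non-decreasing in the threshold", {
  set.seed(8)
  d <- c(10, 10, 10)
  v <- volume3d(array(runif(prod(d), -1000, -700), d), c(1, 1, 1))
  par <- array(TRUE, d)
  lav <- sapply(c(-950, -920, -900, -856), function(th)
    lav_percent(binarize(v, par, th), par))
  expect_true(all(diff(lav) >= 0))
})

test_that("PRM voxel rules match the two emphysema conventions", {
  case <- function(ihu, ehu, rule) {
    tp <- tiny_pair(ihu, ehu)
    prm <- prm_classify(tp$insp, tp$exp, tp$par, thresholds(emph_rule = rule))
    unique(as.integer(prm$class))
  }
  expect_equal(case(-970, -960, "paper_both_950"), 3L) # emphysema
  expect_equal(case(-970, -960, "classic_prm"), 3L)
  expect_equal(case(-900, -900, "paper_both_950"), 2L) # fSAD
  expect_equal(case(-900, -900, "classic_prm"), 2L)
  # divergence: deep inspiratory, recovered expiratory
  expect_equal(case(-970, -900, "paper_both_950"), 2L)
  expect_equal(case(-970, -900, "classic_prm"), 3L)
  expect_equal(case(-800, -800, "paper_both_950"), 1L) # normal
})

test_that("PRM classes are exclusive and cover the effective parenchyma", {
  p <- phantom_pipeline()
  prm <- p$prm
  n_par <- sum(prm$parenchyma)
  expect_equal(sum(prm$class > 0L), n_par)
  expect_equal(sum(prm$counts$global$n), n_par)
  reg <- prm$counts$regional
  expect_equal(sum(reg$n), sum(prm$parenchyma & p$regions_i$group > 0L))
})

test_that("composite LAV sums are consistent and Emph950/fSAD are disjoint", {
  p <- phantom_pipeline()
  prm <- p$prm
  lav <- composite_lav(prm, p$pair$insp, p$reg$coreg, p$regions_i)
  whole <- lav[lav$region == "whole", ]
  expect_equal(whole$lav_emph950_fsad, whole$lav_emph950 + whole$lav_fsad)
  expect_equal(whole$lav_emph920_airt, whole$lav_emph920 + whole$lav_airt)
  # regional rows add up to the whole (shared denominator)
  up_low <- lav[lav$region %in% c("upper", "lower"), ]
  expect_equal(sum(up_low$lav_emph950), whole$lav_emph950, tolerance = 1e-12)
  # disjointness of the PRM classes behind the composite
  emph <- prm$class == 3L
  fsad <- prm$class == 2L
  expect_equal(sum(emph & fsad), 0)
})

test_that("thresholds() validates its ordering and rejects nonsense", {
  expect_error(thresholds(emph_mild = -960), "require")
  th <- thresholds(emph_mild = -930)
  expect_equal(th$emph_mild, -930)
})

test_that("phantom air-trapping LAV% tracks the ground-truth lesion fraction", {
  p <- phantom_pipeline()
  prm <- p$prm
  par_eff <- prm$parenchyma
  lesion <- binarize(p$reg$coreg, par_eff, thresholds()$air_trap)
  airt <- lav_percent(lesion, par_eff)
  truth_frac <- 100 * sum(p$truth$lesion_labels %in% c(1L, 2L) & par_eff) /
    sum(par_eff)
  expect_lt(abs(airt - truth_frac), 1.5)
})
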