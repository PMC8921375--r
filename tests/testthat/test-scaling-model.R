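# Optimal 1-D k-means, scale models, predictor assembly, model fitting,
# backward selection, cross-validation and the Pearson helper.

brute_force_wss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  combs <- utils::combn(n - 1, k - 1)
  for (c in seq_len(ncol(combs))) {
    cuts <- c(0, combs[, c], n)
    w <- sum(vapply(seq_len(k), function(q) ss(x[(cuts[q] + 1):cuts[q + 1]]),
                    numeric(1)))
    if (w < best) best <- w
  }
  best
}

test_that("ckmeans finds obvious optima and handles k = n", {
  f <- ckmeans_1d(c(1, 2, 10, 11), 2)
  expect_equal(f$wss, 1.0)
  expect_equal(sort(unique(f$cluster[1:2])), 1)
  expect_equal(sort(unique(f$cluster[3:4])), 2)
  x <- c(3, 1, 4, 1.5, 9)
  g <- ckmeans_1d(x, 5)
  expect_equal(g$wss, 0)
  expect_error(ckmeans_1d(1:3, 4), "parameter error")
})

test_that("ckmeans equals the exhaustive-partition oracle on random instances", {
  set.seed(1)
  for (t in 1:60) {
    n <- sample(4:12, 1)
    k <- sample(2:4, 1)
    k <- min(k, n)
    x <- round(runif(n, 0, 10), 3)
    expect_equal(ckmeans_1d(x, k)$wss, brute_force_wss(x, k), tolerance = 1e-9)
  }
})

test_that("scale models assign by boundary lookup with clamping", {
  pool <- as.numeric(sapply(1:10, function(s) rep(s, 5))) / 100
  m <- fit_scale_model(pool, k = 10)
  expect_equal(assign_scale(m, 0.031), 3L)
  expect_equal(assign_scale(m, 1e-9), 1L)   # below all training values
  expect_equal(assign_scale(m, 5), 10L)     # above all training values
  expect_true(all(diff(m$boundaries) > 0))
  expect_error(fit_scale_model(rep(0.1, 50), k = 10), "degenerate-scale")
})

test_that("scale boundaries reproduce the optimal DP partition on a log-normal pool", {
  set.seed(2)
  pool <- rlnorm(10000, log(0.002), 1.2)
  m <- fit_scale_model(pool, k = 10)
  reassigned <- assign_scale(m, pool)
  direct <- ckmeans_1d(pool, 10)$cluster
  expect_equal(reassigned, as.integer(direct))
  # exact DP-optimal WSS against the oracle on a small subsample
  sub <- sort(pool)[round(seq(1, 10000, length.out = 12))]
  expect_equal(ckmeans_1d(sub, 4)$wss, brute_force_wss(sub, 4), tolerance = 1e-12)
})

test_that("predictor assembly conserves regional LAV% and handles empty subjects", {
  pool <- c(rlnorm(200, log(0.002), 1.2))
  scales <- list(emph950 = fit_scale_model(pool, 10, "inspiratory"),
                 fsad = fit_scale_model(pool, 10, "expiratory"))
  empty <- assemble_predictors(
    tibble::tibble(type = character(0), group = character(0), lad = numeric(0)),
    scales)
  expect_true(all(as.numeric(empty[predictor_terms()]) == 0))
  one <- assemble_predictors(
    tibble::tibble(type = "emph950", group = "upper", lad = 0.05), scales)
  sc <- assign_scale(scales$emph950, 0.05)
  expect_equal(as.numeric(one[[sprintf("emph950_upper_s%02d", sc)]]), 5)
  expect_equal(sum(as.numeric(one[predictor_terms()])), 5)
  set.seed(3)
  recs <- tibble::tibble(type = sample(c("emph950", "fsad"), 50, TRUE),
                         group = sample(c("upper", "lower"), 50, TRUE),
                         lad = rlnorm(50, log(0.002), 1.2))
  x <- assemble_predictors(recs, scales)
  for (tp in c("emph950", "fsad")) for (gr in c("upper", "lower")) {
    cols <- sprintf("%s_%s_s%02d", tp, gr, 1:10)
    expect_equal(sum(as.numeric(x[cols])),
                 100 * sum(recs$lad[recs$type == tp & recs$group == gr]),
                 tolerance = 1e-12)
  }
})

test_that("the full model recovers exact linear data and degenerate designs", {
  terms <- predictor_terms()
  set.seed(4)
  n <- 60
  X <- matrix(0, n, 40, dimnames = list(NULL, terms))
  X[, 1] <- runif(n, 0, 10)
  d <- tibble::as_tibble(cbind(as.data.frame(X), fev1_fvc = 70 - 2 * X[, 1]))
  fit <- suppressWarnings(fit_full_model(d))
  expect_equal(unname(coef(fit$fit)[terms[1]]), -2, tolerance = 1e-9)
  # all-zero predictors: intercept = mean(y)
  d2 <- tibble::as_tibble(cbind(as.data.frame(matrix(0, n, 40,
                                                     dimnames = list(NULL, terms))),
                                fev1_fvc = rnorm(n, 55, 5)))
  fit2 <- suppressWarnings(fit_full_model(d2))
  expect_equal(unname(coef(fit2$fit)[["(Intercept)"]]), mean(d2$fev1_fvc))
  expect_error(fit_full_model(d[1:10, ]), "fit error")
})

test_that("backward selection keeps a strong true predictor and prunes noise at ~alpha", {
  set.seed(5)
  terms6 <- predictor_terms()[1:6]
  kept_true <- 0
  noise_kept <- 0
  runs <- 100
  for (r in seq_len(runs)) {
    X <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, terms6))
    y <- 60 - 3 * X[, 1] + rnorm(200, 0, 2)
    d <- tibble::as_tibble(cbind(as.data.frame(X), fev1_fvc = y))
    m <- suppressWarnings(backward_select(fit_full_model(d, terms = terms6)))
    kept_true <- kept_true + (terms6[1] %in% m$terms$term)
    noise_kept <- noise_kept + sum(terms6[-1] %in% m$terms$term)
  }
  expect_equal(kept_true, runs)
  rate <- noise_kept / (runs * 5)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("all-noise designs collapse to the intercept-only model at roughly (1-alpha)^p", {
  set.seed(6)
  terms5 <- predictor_terms()[1:5]
  none <- 0
  runs <- 100
  for (r in seq_len(runs)) {
    X <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, terms5))
    d <- tibble::as_tibble(cbind(as.data.frame(X), fev1_fvc = rnorm(120, 55, 8)))
    m <- suppressWarnings(backward_select(fit_full_model(d, terms = terms5)))
    none <- none + (nrow(m$terms) == 0)
  }
  expect_gt(none / runs, 0.6)  # (1 - 0.05)^5 ~ 0.77, allow MC slack
  expect_lt(none / runs, 0.95)
})

test_that("an already-valid model is a fixed point of backward selection", {
  set.seed(7)
  terms2 <- predictor_terms()[1:2]
  X <- matrix(rnorm(300 * 2), 300, 2, dimnames = list(NULL, terms2))
  y <- 50 - 4 * X[, 1] + 3 * X[, 2] + rnorm(300, 0, 1)
  d <- tibble::as_tibble(cbind(as.data.frame(X), fev1_fvc = y))
  full <- fit_full_model(d, terms = terms2)
  m <- backward_select(full)
  expect_setequal(m$terms$term, terms2)
  expect_equal(sort(m$terms$estimate), sort(coef(full$fit)[terms2]),
               ignore_attr = TRUE)
})

test_that("tidy/glance/predict expose the airflow model in broom style", {
  co <- make_cohort(100, seed = 3)
  m <- suppressWarnings(backward_select(fit_full_model(co)))
  td <- tidy(m)
  expect_true(all(c("term", "scale", "group", "type", "estimate", "p_value")
                  %in% names(td)))
  expect_true(all(td$p_value < m$alpha))
  gl <- glance(m)
  expect_equal(gl$n_terms, nrow(td))
  pred <- predict(m, co)
  expect_equal(length(pred), nrow(co))
  expect_gt(cor(pred, co$fev1_fvc), 0.7)
})

test_that("pearson matches the closed-form computation and validates input", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 9)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  out <- pearson(a, b)
  expect_equal(out$r, r_hand)
  expect_equal(out$p, p_hand)
  expect_equal(pearson(a, a)$r, 1.0)
  expect_equal(pearson(a, -a)$r, -1.0)
  expect_error(pearson(a, rep(1, 4)), "zero variance")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("cross-validation is perfect on noiseless data and null on permuted labels", {
  truth0 <- default_cohort_truth()
  truth0$noise_sd <- 0
  co <- make_cohort(60, truth0, seed = 9)
  co <- co[co$fev1_fvc > 10 & co$fev1_fvc < 95, ]
  cv <- cross_validate(co, folds = 5, repeats = 3, seed = 1)
  expect_true(all(cv$r > 0.999))
  # permutation null
  co2 <- make_cohort(60, seed = 10)
  set.seed(11)
  co2$fev1_fvc <- sample(co2$fev1_fvc)
  cv2 <- suppressWarnings(cross_validate(co2, folds = 5, repeats = 10, seed = 2))
  expect_lt(abs(attr(cv2, "mean_r")), 0.15)
})

test_that("cohort examples: noiseless laws are exact and R2 calibration holds", {
  # single nonzero beta, zero noise: exact affine response
  tr <- cohort_truth(
    beta = tibble::tibble(term = "emph950_upper_s03", beta = -0.5),
    intercept = 75, noise_sd = 0,
    boundaries = default_cohort_truth()$boundaries)
  co <- make_cohort(30, tr, seed = 1)
  inside <- co$fev1_fvc > 10 & co$fev1_fvc < 95
  expect_equal(co$fev1_fvc[inside],
               (75 - 0.5 * co$emph950_upper_s03)[inside], tolerance = 1e-12)
  # all-zero betas: constant response
  tr0 <- cohort_truth(beta = tibble::tibble(term = character(0), beta = numeric(0)),
                      intercept = 75, noise_sd = 0,
                      boundaries = default_cohort_truth()$boundaries)
  co0 <- make_cohort(12, tr0, seed = 2)
  expect_true(all(co0$fev1_fvc == 75))
  expect_error(make_cohort(5, tr0), "at least 10")
  tr_bad <- tr0; tr_bad$noise_sd <- -1
  expect_error(make_cohort(20, tr_bad), "parameter error")
  # Monte-Carlo: mean sample r between the linear predictor and the response
  # stays within +/- 0.08 of sqrt(target R2) over 30 seeds
  rs <- vapply(1:30, function(s) {
    cs <- make_cohort(100, seed = s)
    cor(attr(cs, "linpred"), cs$fev1_fvc)
  }, numeric(1))
  expect_lt(abs(mean(rs) - sqrt(0.67)), 0.08)
})
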