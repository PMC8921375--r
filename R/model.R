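# The airflow-limitation linear model: 40 predictors — 10 LAD size scales x
# {upper, lower} lobe group x {inspiratory emphysema (−950), expiratory fSAD}
# — fitted by OLS and reduced by backward selection until every retained
# predictor has p < alpha, evaluated by repeated stratified 5-fold CV.

#' The 40 predictor term names
#'
#' Terms are named `<type>_<group>_s<scale>`; the canonical order is scale
#' fastest, then group (upper, lower), then type (emph950, fsad).
#'
#' @param k number of scales.
#' @return Character vector of term names (length `4 * k`).
#' @export
predictor_terms <- function(k = 10) {
  g <- expand.grid(scale = seq_len(k), group = c("upper", "lower"),
                   type = c("emph950", "fsad"), stringsAsFactors = FALSE)
  sprintf("%s_%s_s%02d", g$type, g$group, g$scale)
}

parse_term <- function(term) {
  m <- regmatches(term, regexec("^(emph950|fsad)_(upper|lower)_s(\\d+)$", term))
  tibble::tibble(
    term = term,
    type = vapply(m, `[`, "", 2),
    group = vapply(m, `[`, "", 3),
    scale = as.integer(vapply(m, `[`, "", 4))
  )
}

#' Cluster records for one subject's predictors
#'
#' Combines the inspiratory severe-emphysema LACs and the classified
#' expiratory clusters into the per-cluster records the predictor assembly
#' consumes: emphysema-predominant expiratory clusters are excluded, and
#' fSAD clusters contribute their effective (PRM fSAD voxel) LAD.
#'
#' @param lacs_insp inspiratory LAC tibble (after [assign_regions()]).
#' @param lacs_exp classified expiratory LAC tibble (after
#'   [classify_lac_predominance()] and [assign_regions()]).
#' @return A tibble with columns `type`, `group`, `lad` (one row per
#'   contributing cluster) plus the source ids.
#' @export
lac_predictor_records <- function(lacs_insp, lacs_exp) {
  a <- if (nrow(lacs_insp)) {
    tibble::tibble(type = "emph950", group = lacs_insp$group,
                   lad = lacs_insp$lad, phase = "inspiratory",
                   id = lacs_insp$id)
  } else tibble::tibble(type = character(0), group = character(0),
                        lad = numeric(0), phase = character(0), id = integer(0))
  keep <- lacs_exp$lac_class == "fsad"
  b <- if (any(keep)) {
    tibble::tibble(type = "fsad", group = lacs_exp$group[keep],
                   lad = lacs_exp$lad_eff[keep], phase = "expiratory",
                   id = lacs_exp$id[keep])
  } else tibble::tibble(type = character(0), group = character(0),
                        lad = numeric(0), phase = character(0), id = integer(0))
  dplyr::bind_rows(a, b)
}

#' Assemble the 40-predictor vector for one subject
#'
#' `x[(s, g, t)] = 100 * sum of LAD` over the subject's clusters with scale
#' `s`, lobe group `g` and lesion type `t` (zero when none), so summing a
#' type/group's scales reproduces that regional LAV% exactly.
#'
#' @param records cluster records from [lac_predictor_records()] (or
#'   [make_cohort()] detail), columns `type`, `group`, `lad`.
#' @param scales named list of [fit_scale_model()] objects, one per type
#'   (`emph950`, `fsad`).
#' @param subject_id identifier stored in the output.
#' @return A one-row tibble: `subject_id` plus the 40 predictor columns (LAD%
#'   units).
#' @export
assemble_predictors <- function(records, scales, subject_id = NA_character_) {
  terms <- predictor_terms(scales[[1]]$k)
  x <- setNames(numeric(length(terms)), terms)
  if (nrow(records) > 0) {
    sc <- integer(nrow(records))
    for (tp in unique(records$type)) {
      sel <- records$type == tp
      sc[sel] <- assign_scale(scales[[tp]], records$lad[sel])
    }
    key <- sprintf("%s_%s_s%02d", records$type, records$group, sc)
    agg <- tapply(100 * records$lad, key, sum)
    x[names(agg)] <- agg
  }
  tibble::as_tibble(c(list(subject_id = subject_id), as.list(x)))
}

#' Fit the full 40-predictor linear model
#'
#' Ordinary least squares of FEV1/FVC% on all predictor columns, with
#' two-sided t-test p-values per coefficient. Rank-deficient columns are
#' dropped with a warning.
#'
#' @param data tibble with the predictor columns and the response.
#' @param response response column name (default `fev1_fvc`).
#' @param terms predictor column names (default: every [predictor_terms()]
#'   column present).
#' @return Object of class `airflow_fit` wrapping the `lm` fit.
#' @export
fit_full_model <- function(data, response = "fev1_fvc", terms = NULL) {
  if (is.null(terms)) terms <- intersect(predictor_terms(), names(data))
  assert_that(length(terms) > 0, "no predictor columns found")
  n <- nrow(data)
  assert_that(n > length(terms) + 1,
              paste0("fit error: n (", n, ") must exceed predictors + 1 (",
                     length(terms) + 1, "); reduce predictors first"))
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = data)
  dropped <- names(which(is.na(coef(fit))))
  if (length(dropped) > 0) {
    warning("dropping rank-deficient columns: ", paste(dropped, collapse = ", "))
    terms <- setdiff(terms, dropped)
    fml <- stats::as.formula(paste(
      response, "~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
    fit <- lm(fml, data = data)
  }
  structure(list(fit = fit, terms = terms, response = response, data = data),
            class = "airflow_fit")
}

fit_pvalues <- function(x) {
  s <- summary(x$fit)$coefficients
  p <- s[, "Pr(>|t|)"]
  p[setdiff(rownames(s), "(Intercept)")]
}

#' Backward selection to an all-significant model
#'
#' Repeatedly refits after removing the single highest-p predictor until all
#' remaining predictors have p < `alpha` (the intercept is always kept).
#' Equal p-values are broken deterministically by removing the
#' largest-index column first. If everything is removed, the intercept-only
#' model is returned with a warning.
#'
#' @param full an [fit_full_model()] object.
#' @param alpha significance level (default 0.05).
#' @return Object of class `airflow_model`: `intercept`, `terms` tibble
#'   (term, scale, group, type, estimate, p_value), `alpha` and the final
#'   `lm` fit.
#' @export
backward_select <- function(full, alpha = 0.05) {
  stopifnot(inherits(full, "airflow_fit"))
  terms <- full$terms
  data <- full$data
  response <- full$response
  order_ref <- terms
  fit <- full$fit
  repeat {
    if (length(terms) == 0) break
    fml <- stats::as.formula(paste(response, "~",
                                   paste(terms, collapse = " + ")))
    fit <- lm(fml, data = data)
    p <- fit_pvalues(list(fit = fit))
    p <- p[terms[terms %in% names(p)]]
    if (length(p) == 0 || all(p < alpha, na.rm = TRUE)) break
    p[is.na(p)] <- Inf
    worst <- max(p)
    cand <- names(p)[p >= worst - 1e-15]
    # deterministic tie-break: largest column index goes first
    drop_term <- cand[which.max(match(cand, order_ref))]
    terms <- setdiff(terms, drop_term)
  }
  if (length(terms) == 0) {
    warning("backward selection removed every predictor; intercept-only model")
    fit <- lm(stats::as.formula(paste(response, "~ 1")), data = data)
    term_tbl <- parse_term(character(0))
    term_tbl$estimate <- numeric(0)
    term_tbl$p_value <- numeric(0)
  } else {
    cf <- coef(fit)
    p <- fit_pvalues(list(fit = fit))
    term_tbl <- parse_term(terms)
    term_tbl$estimate <- as.numeric(cf[terms])
    term_tbl$p_value <- as.numeric(p[terms])
  }
  structure(list(intercept = as.numeric(coef(fit)[["(Intercept)"]]),
                 terms = term_tbl, alpha = alpha, fit = fit,
                 response = response),
            class = "airflow_model")
}

#' @export
print.airflow_model <- function(x, ...) {
  cat(sprintf("<airflow_model> FEV1/FVC%% ~ intercept %.2f + %d LAD-scale terms (all p < %.2g)\n",
              x$intercept, nrow(x$terms), x$alpha))
  invisible(x)
}

#' @export
#' @rdname backward_select
#' @param x an `airflow_model`.
#' @param ... unused.
tidy.airflow_model <- function(x, ...) x$terms

#' @export
#' @rdname backward_select
glance.airflow_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, n = length(s$residuals) + sum(is.na(x$fit$residuals)) * 0,
    n_terms = nrow(x$terms), alpha = x$alpha
  )
}

#' Predict FEV1/FVC% from assembled predictors
#'
#' @param object an `airflow_model`.
#' @param newdata tibble with the predictor columns (LAD% units).
#' @param ... unused.
#' @return Numeric vector of predicted FEV1/FVC%.
#' @export
predict.airflow_model <- function(object, newdata, ...) {
  out <- rep(object$intercept, nrow(newdata))
  for (r in seq_len(nrow(object$terms))) {
    out <- out + object$terms$estimate[r] * newdata[[object$terms$term[r]]]
  }
  out
}

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation and the two-sided t-distribution p-value.
#'
#' @param a,b numeric vectors of equal length (n >= 3, nonzero variance).
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
pearson <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  assert_that(length(a) >= 3, "need at least 3 observations")
  assert_that(sd(a) > 0 && sd(b) > 0,
              "undefined-correlation error: zero variance")
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

cv_fold_ids <- function(y, folds, seed) {
  n <- length(y)
  qs <- quantile(y, probs = seq(0, 1, 0.2), type = 7)
  strata <- cut(y, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  strata[is.na(strata)] <- 1L
  fold <- integer(n)
  with_stream_seed(seed, "cv-folds", {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation of the airflow model
#'
#' Per repeat: subjects are shuffled (seeded) into folds stratified by
#' response quintile; for each fold the full model is fitted and
#' backward-selected on the training portion and applied to the held-out
#' subjects; the per-repeat Pearson r is computed on the pooled out-of-fold
#' predictions.
#'
#' @param data tibble of predictors and response (e.g. [make_cohort()]).
#' @param folds,repeats CV layout (default 5 x 30).
#' @param seed integer seed driving every shuffle.
#' @param alpha backward-selection significance level.
#' @param response response column.
#' @param reselect if `FALSE`, the model is selected once on the full data
#'   and only refitted per fold (the default `TRUE` reselects per fold).
#' @return A tibble with one row per repeat (`repeat`, `r`); per-fold rows
#'   (repeat, fold, n_test, r) in attribute `folds`, mean/sd as attributes
#'   `mean_r`, `sd_r`.
#' @export
cross_validate <- function(data, folds = 5, repeats = 30, seed = 1,
                           alpha = 0.05, response = "fev1_fvc",
                           reselect = TRUE) {
  y <- data[[response]]
  n <- length(y)
  assert_that(n >= folds, "parameter error: more folds than subjects")
  assert_that(floor(n / folds) >= 2, "parameter error: a fold would have < 2 subjects")
  terms_all <- intersect(predictor_terms(), names(data))
  fixed_terms <- NULL
  if (!reselect) {
    fixed_terms <- backward_select(fit_full_model(data, response, terms_all),
                                   alpha)$terms$term
  }
  rep_rows <- list()
  fold_rows <- list()
  for (rp in seq_len(repeats)) {
    fold <- cv_fold_ids(y, folds, derive_seed(seed, paste0("cv-repeat-", rp)))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      test <- fold == f
      train <- !test
      if (!is.null(fixed_terms)) {
        terms_f <- fixed_terms
        if (length(terms_f) == 0) {
          pred[test] <- mean(y[train])
          next
        }
        fml <- stats::as.formula(paste(response, "~",
                                       paste(terms_f, collapse = " + ")))
        fit <- lm(fml, data = data[train, , drop = FALSE])
        cf <- coef(fit)
        pred[test] <- as.numeric(cf[1]) +
          as.matrix(data[test, terms_f, drop = FALSE]) %*%
          ifelse(is.na(cf[terms_f]), 0, cf[terms_f])
      } else {
        # per-fold refits repeat the same rank-deficiency notes; keep quiet here
        full <- suppressWarnings(fit_full_model(data[train, , drop = FALSE],
                                                response, terms_all))
        mdl <- suppressWarnings(backward_select(full, alpha))
        pred[test] <- predict(mdl, data[test, , drop = FALSE])
      }
      r_fold <- if (sd(pred[test]) > 0 && sd(y[test]) > 0)
        cor(pred[test], y[test]) else NA_real_
      fold_rows[[length(fold_rows) + 1]] <-
        tibble::tibble(repeat_ = rp, fold = f, n_test = sum(test), r = r_fold)
    }
    r_rep <- cor(pred, y)
    rep_rows[[rp]] <- tibble::tibble(repeat_ = rp, r = r_rep)
  }
  out <- dplyr::bind_rows(rep_rows)
  attr(out, "folds") <- dplyr::bind_rows(fold_rows)
  attr(out, "mean_r") <- mean(out$r)
  attr(out, "sd_r") <- sd(out$r)
  out
}

#' Serialize an airflow model (with its scale models) to JSON
#'
#' @param model an `airflow_model`.
#' @param scales named list of `scale_model`s used to build its predictors.
#' @param path output JSON path.
#' @param seed seed recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_airflow_model <- function(model, scales, path, seed = NA) {
  obj <- list(
    intercept = model$intercept,
    alpha = model$alpha,
    terms = model$terms,
    scales = lapply(scales, function(s)
      list(k = s$k, boundaries = s$boundaries, centers = s$centers,
           provenance = s$provenance)),
    seed = seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an airflow model written by [write_airflow_model()]
#'
#' @param path JSON path.
#' @return List with `model` (an `airflow_model` without the `lm` fit) and
#'   `scales`.
#' @export
read_airflow_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- tibble::as_tibble(obj$terms)
  model <- structure(list(intercept = obj$intercept, terms = terms,
                          alpha = obj$alpha, fit = NULL,
                          response = "fev1_fvc"),
                     class = "airflow_model")
  scales <- lapply(obj$scales, function(s) {
    structure(list(k = s$k, boundaries = as.numeric(s$boundaries),
                   centers = as.numeric(s$centers), sizes = NULL, wss = NULL,
                   provenance = s$provenance),
              class = "scale_model")
  })
  list(model = model, scales = scales)
}
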