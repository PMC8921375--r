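# Pipeline configuration and the two entry points: single-subject severity
# mapping and cohort model building. Every stage is deterministic given the
# configuration and seed; a provenance record (config + seed + versions) is
# written next to the outputs.

#' Pipeline configuration
#'
#' Nested list of every tunable parameter with the package defaults. Values
#' round-trip losslessly through YAML via [write_config()] / [read_config()].
#'
#' @param ... named overrides of top-level sections (lists are merged
#'   shallowly).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    thresholds = list(emph_mild = -920, emph_severe = -950, air_trap = -856,
                      emph_rule = "paper_both_950"),
    segmentation = list(upper_bound_hu = -200, connectivity = 26,
                        closing_iter = 2, leak_factor = 3,
                        fissure_sigma_mm = 1, fissure_threshold = NA,
                        fallback_height = 0.55),
    registration = list(beta = 20, lambda = 3, outlier_w = 0.1, pitch = 8,
                        max_iter = 150, tol = 1e-5, coarse_mm = 4),
    lac = list(connectivity = 26, min_core_depth = 2, ratio_cut = 0.5,
               min_voxels = 8),
    model = list(k = 10, alpha = 0.05, folds = 5, repeats = 30, seed = 1),
    grid = list(cell_size = 20)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

thresholds_from_config <- function(config) {
  tc <- config$thresholds
  thresholds(emph_mild = tc$emph_mild, emph_severe = tc$emph_severe,
             air_trap = tc$air_trap, emph_rule = tc$emph_rule)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

write_provenance <- function(dir, config, seed) {
  jsonlite::write_json(
    list(package = "bprm",
         version = as.character(utils::packageVersion("bprm")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = seed, config = unclass(config)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(NULL)
}

#' Run the full single-subject pipeline
#'
#' Segmentation → registration → PRM → LAC extraction → predictor assembly →
#' BPRM grid, in the pipeline order lung mask segmentation, 3-D non-rigid
#' point-set registration and image deformation. The report carries the
#' regional LAV% table, LAC counts, the predicted FEV1/FVC% and the
#' conservation residual of the severity grid.
#'
#' @param insp,exp inspiratory/expiratory inputs: [volume3d]s or NIfTI paths.
#' @param model a model JSON path (from [run_cohort()]), or a list with
#'   elements `model` (`airflow_model`) and `scales`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for masks, PRM, LAC tables, the
#'   BPRM map and the JSON report (partial outputs are retained on stage
#'   failure).
#' @return A list of class `subject_result`: `report` (plain list, fully
#'   deterministic), plus the intermediate objects (`regions`, `coreg`,
#'   `prm`, `lacs_insp`, `lacs_exp`, `predictors`, `grid`).
#' @export
run_subject <- function(insp, exp, model, config = pipeline_config(),
                        out_dir = NULL) {
  if (is.character(insp)) insp <- read_volume(insp, phase = "inspiratory")
  if (is.character(exp)) exp <- read_volume(exp, phase = "expiratory")
  if (is.character(model)) model <- read_airflow_model(model)
  th <- thresholds_from_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_vol <- function(x, name, datatype = "uint8") {
    if (!is.null(out_dir))
      write_volume(x, file.path(out_dir, name), geometry = insp,
                   datatype = datatype)
  }

  regions_insp <- run_stage("segmentation (inspiratory)", segment_subject(insp, config))
  regions_exp <- run_stage("segmentation (expiratory)", segment_subject(exp, config))
  mean_insp <- mean(insp$values[regions_insp$side > 0L])
  mean_exp <- mean(exp$values[regions_exp$side > 0L])
  if (mean_exp <= mean_insp)
    warning("expiratory mean lung HU is not above inspiratory; ",
            "inspiratory/expiratory inputs may be swapped")
  save_vol(regions_insp$side + 0, "side_insp.nii.gz")
  save_vol(regions_insp$group + 0, "group_insp.nii.gz")
  save_vol(regions_insp$airway + 0, "airway_insp.nii.gz")

  reg <- run_stage("registration", register_pair(insp, exp, regions_insp,
                                                 regions_exp, config))
  coreg <- reg$coreg
  save_vol(coreg$values, "coreg_exp.nii.gz", datatype = "float")

  parenchyma <- parenchyma_mask(regions_insp)
  prm <- run_stage("prm", prm_classify(insp, coreg, parenchyma, th,
                                       regions = regions_insp))
  save_vol(prm$class + 0, "prm.nii.gz")
  par_eff <- prm$parenchyma
  n_par <- sum(par_eff)
  lav <- run_stage("densitometry", composite_lav(prm, insp, coreg, regions_insp))

  lc <- config$lac
  lesion_insp <- binarize(insp, par_eff, th$emph_severe)
  lacs_insp <- run_stage("lac (inspiratory)", {
    l <- extract_lacs(lesion_insp, min_core_depth = lc$min_core_depth,
                      connectivity = lc$connectivity,
                      parenchyma_count = n_par, geometry = insp,
                      phase = "inspiratory", threshold = th$emph_severe,
                      min_voxels = lc$min_voxels)
    assign_regions(l, regions_insp)
  })
  lesion_exp <- binarize(coreg, par_eff, th$air_trap)
  lacs_exp <- run_stage("lac (expiratory)", {
    l <- extract_lacs(lesion_exp, min_core_depth = lc$min_core_depth,
                      connectivity = lc$connectivity,
                      parenchyma_count = n_par, geometry = insp,
                      phase = "expiratory", threshold = th$air_trap,
                      min_voxels = lc$min_voxels)
    l <- classify_lac_predominance(l, prm, ratio_cut = lc$ratio_cut)
    assign_regions(l, regions_insp)
  })
  if (!is.null(out_dir)) {
    write_lac_csv(lacs_insp, file.path(out_dir, "lacs_insp.csv"))
    write_lac_csv(lacs_exp, file.path(out_dir, "lacs_exp.csv"))
  }

  records <- lac_predictor_records(lacs_insp, lacs_exp)
  predictors <- run_stage("predictors",
                          assemble_predictors(records, model$scales, "subject"))
  predicted <- predict(model$model, predictors)

  contrib <- run_stage("bprm", voxel_contribution(lacs_insp, lacs_exp, prm,
                                                  model$model, model$scales,
                                                  n_par))
  grid <- aggregate_grid(contrib, regions_insp, prm, insp, model$model,
                         cell_size = config$grid$cell_size)
  if (!is.null(out_dir))
    export_bprm(grid, insp, file.path(out_dir, "bprm.nii.gz"),
                file.path(out_dir, "bprm_cells.csv"))

  conservation <- abs(grid$whole_lung_prediction - predicted) /
    max(abs(predicted), 1e-12)
  report <- list(
    parenchyma_voxels = n_par,
    mean_lung_hu = list(inspiratory = mean_insp, expiratory = mean_exp),
    lav = as.data.frame(lav),
    prm_percent = list(
      normal = 100 * sum(prm$class == 1L) / n_par,
      fsad = 100 * sum(prm$class == 2L) / n_par,
      emphysema = 100 * sum(prm$class == 3L) / n_par
    ),
    n_lacs = list(inspiratory = nrow(lacs_insp), expiratory = nrow(lacs_exp),
                  fsad = sum(lacs_exp$lac_class == "fsad")),
    predicted_fev1_fvc = predicted,
    bprm = list(n_cells = nrow(grid$cells), cell_size = grid$cell_size,
                total_severity = sum(grid$cells$severity),
                intercept = grid$intercept,
                conservation_rel_error = conservation)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_provenance(out_dir, config, config$model$seed)
  }
  structure(list(report = report, regions = regions_insp,
                 regions_exp = regions_exp, coreg = coreg, prm = prm,
                 lav = lav, lacs_insp = lacs_insp, lacs_exp = lacs_exp,
                 predictors = predictors, grid = grid,
                 registration = reg["landmarks"]),
            class = "subject_result")
}

#' Build the airflow model from a cohort of cluster tables
#'
#' Pools the per-cluster LADs per lesion type, fits the two 10-scale size
#' models, assembles each subject's 40 predictors, fits the full linear model
#' of FEV1/FVC%, reduces it by backward selection, and evaluates by repeated
#' stratified five-fold cross-validation.
#'
#' @param clusters tibble of per-cluster records: `subject_id`, `type`
#'   (`emph950`/`fsad`), `group` (`upper`/`lower`), `lad` — e.g. the
#'   `clusters` attribute of [make_cohort()] or rows read from per-subject
#'   LAC CSVs.
#' @param spirometry tibble `subject_id`, `fev1_fvc`; subjects with missing
#'   spirometry are skipped with a message.
#' @param config a [pipeline_config()].
#' @param seed integer seed for the CV shuffles (default from config).
#' @param out_dir optional directory for `model.json`, `cv_report.csv` and
#'   provenance.
#' @return A list of class `cohort_result`: `scales`, `model`
#'   (`airflow_model`), `cv` (per-repeat tibble with per-fold attribute),
#'   `predictors` (the assembled table).
#' @export
run_cohort <- function(clusters, spirometry, config = pipeline_config(),
                       seed = config$model$seed, out_dir = NULL) {
  mc <- config$model
  ids <- unique(clusters$subject_id)
  keep <- ids %in% spirometry$subject_id[!is.na(spirometry$fev1_fvc)]
  if (any(!keep))
    message("skipping ", sum(!keep), " subject(s) with missing spirometry")
  ids <- ids[keep]
  assert_that(length(ids) >= 2, "fit error: need at least 2 subjects")
  clusters <- clusters[clusters$subject_id %in% ids, , drop = FALSE]
  scales <- list(
    emph950 = fit_scale_model(clusters$lad[clusters$type == "emph950"],
                              k = mc$k, provenance = "inspiratory"),
    fsad = fit_scale_model(clusters$lad[clusters$type == "fsad"],
                           k = mc$k, provenance = "expiratory")
  )
  preds <- dplyr::bind_rows(lapply(ids, function(id) {
    assemble_predictors(clusters[clusters$subject_id == id, , drop = FALSE],
                        scales, subject_id = id)
  }))
  data <- dplyr::inner_join(preds, spirometry, by = "subject_id")
  full <- fit_full_model(data, response = "fev1_fvc")
  model <- suppressWarnings(backward_select(full, alpha = mc$alpha))
  cv <- cross_validate(data, folds = mc$folds, repeats = mc$repeats,
                       seed = seed, alpha = mc$alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_airflow_model(model, scales, file.path(out_dir, "model.json"),
                        seed = seed)
    utils::write.csv(as.data.frame(attr(cv, "folds")),
                     file.path(out_dir, "cv_report.csv"), row.names = FALSE)
    write_provenance(out_dir, config, seed)
  }
  structure(list(scales = scales, model = model, cv = cv,
                 predictors = data),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, %d selected terms, CV mean r = %.3f\n",
              nrow(x$predictors), nrow(x$model$terms), attr(x$cv, "mean_r")))
  invisible(x)
}

#' Train a model on a synthetic cohort and run a phantom subject through it
#'
#' Convenience wrapper used in examples and end-to-end checks: builds a
#' [make_cohort()] cohort, fits the airflow model via [run_cohort()], and
#' returns the model bundle ready for [run_subject()].
#'
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @return A list with `model`, `scales` and the `cohort_result`.
#' @export
train_synthetic_model <- function(n_subjects = 100, seed = 1,
                                  config = pipeline_config()) {
  cohort <- make_cohort(n_subjects, seed = seed, detail = TRUE)
  clusters <- attr(cohort, "clusters")
  spiro <- cohort[, c("subject_id", "fev1_fvc")]
  res <- run_cohort(clusters, spiro, config, seed = seed)
  list(model = res$model, scales = res$scales, cohort_result = res)
}
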