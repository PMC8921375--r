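# The bullous parametric response map: distribute the fitted model's
# predicted FEV1/FVC% deviation over lesion voxels and aggregate it on an
# axis-aligned lung grid. "Severity" of a cell is its signed share of the
# whole-lung predicted deviation from the model intercept; conservation
# (cell totals + intercept = subject prediction) is the defining property.

#' Per-voxel severity contributions
#'
#' Each voxel of a LAC whose (scale, group, type) term survived backward
#' selection contributes `beta * 100 / parenchyma_count` FEV1/FVC% — so the
#' voxels of one LAC sum exactly to `beta * LAD%` of that LAC. Inspiratory
#' emphysema LACs paint all their voxels; fSAD LACs paint only their PRM
#' fSAD voxels (their effective LAD); normal voxels and voxels of unselected
#' terms contribute zero.
#'
#' @param lacs_insp inspiratory LAC tibble (regions assigned, `labels`
#'   attribute present).
#' @param lacs_exp classified expiratory LAC tibble (`labels` attribute).
#' @param prm a [prm_classify()] result (for fSAD voxel restriction).
#' @param model an `airflow_model`.
#' @param scales named list of `scale_model`s (`emph950`, `fsad`).
#' @param parenchyma_count whole-lung parenchyma voxel count.
#' @return Numeric array of per-voxel contributions (FEV1/FVC% units).
#' @export
voxel_contribution <- function(lacs_insp, lacs_exp, prm, model, scales,
                               parenchyma_count) {
  lab_i <- attr(lacs_insp, "labels")
  lab_e <- attr(lacs_exp, "labels")
  assert_that(!is.null(lab_i) && !is.null(lab_e),
              "catalog error: LAC tables must carry label maps")
  contrib <- array(0, dim(lab_i))
  term_of <- function(type, group, scale) sprintf("%s_%s_s%02d", type, group, scale)
  beta_of <- setNames(model$terms$estimate, model$terms$term)
  if (nrow(lacs_insp) > 0) {
    assert_that(!is.null(lacs_insp$group), "catalog error: LAC without region")
    sc <- assign_scale(scales$emph950, lacs_insp$lad)
    tm <- term_of("emph950", lacs_insp$group, sc)
    bt <- beta_of[tm]
    per_vox <- ifelse(is.na(bt), 0, bt) * 100 / parenchyma_count
    lut <- numeric(max(lacs_insp$id))
    lut[lacs_insp$id] <- per_vox
    sel <- lab_i > 0L
    contrib[sel] <- contrib[sel] + lut[lab_i[sel]]
  }
  keep <- nrow(lacs_exp) > 0 & any(lacs_exp$lac_class == "fsad")
  if (isTRUE(keep)) {
    fs <- lacs_exp[lacs_exp$lac_class == "fsad", , drop = FALSE]
    assert_that(!is.null(fs$group), "catalog error: LAC without region")
    sc <- assign_scale(scales$fsad, fs$lad_eff)
    tm <- term_of("fsad", fs$group, sc)
    bt <- beta_of[tm]
    per_vox <- ifelse(is.na(bt), 0, bt) * 100 / parenchyma_count
    lut <- numeric(max(fs$id))
    lut[fs$id] <- per_vox
    sel <- lab_e > 0L & prm$class == 2L
    sel_ids <- lab_e[sel]
    vals <- numeric(length(sel_ids))
    known <- sel_ids <= length(lut)
    vals[known] <- lut[sel_ids[known]]
    contrib[sel] <- contrib[sel] + vals
  }
  contrib
}

#' Aggregate severity contributions on a lung grid
#'
#' Axis-aligned cubic cells of edge `cell_size` mm, anchored at the lung
#' bounding-box corner; each cell accumulates its voxels' severity
#' contributions and records its parenchyma count and PRM class composition.
#' Cells are ranked ascending by severity (most negative = most severe).
#'
#' @param contrib per-voxel contributions from [voxel_contribution()].
#' @param regions a [region_mask].
#' @param prm a [prm_classify()] result (class composition).
#' @param geometry a [volume3d] for physical coordinates.
#' @param model the `airflow_model` (intercept recorded for conservation).
#' @param cell_size cell edge in mm (>= voxel spacing).
#' @return Object of class `bprm_grid`: `cells` tibble (cell indices,
#'   centroid mm, side, group, `n_parenchyma`, `severity`, composition
#'   fractions, `rank`), `cell_size`, `intercept`,
#'   `whole_lung_prediction` = intercept + total severity, and the per-voxel
#'   cell id map in attribute `cell_map`.
#' @export
aggregate_grid <- function(contrib, regions, prm, geometry, model,
                           cell_size = 20) {
  assert_that(cell_size >= max(geometry$spacing),
              "cell_size must be at least the voxel spacing")
  d <- dim(contrib)
  lung <- regions$side > 0L
  sel <- which(lung)
  assert_that(length(sel) > 0, "empty lung mask")
  vox <- arrayInd(sel, d)
  mm <- sweep(sweep(vox - 1, 2, geometry$spacing, `*`), 2, geometry$origin, `+`)
  anchor <- apply(mm, 2, min)
  cell_ijk <- floor(sweep(mm, 2, anchor, `-`) / cell_size)
  key <- cell_ijk[, 1] * 1e6 + cell_ijk[, 2] * 1e3 + cell_ijk[, 3]
  uk <- sort(unique(key))
  cid <- factor(match(key, uk), levels = seq_along(uk))
  par_eff <- prm$parenchyma[sel]
  sev <- tapply(contrib[sel], cid, sum)
  n_par <- tapply(par_eff, cid, sum)
  n_emph <- tapply(prm$class[sel] == 3L, cid, sum)
  n_fsad <- tapply(prm$class[sel] == 2L, cid, sum)
  n_norm <- tapply(prm$class[sel] == 1L, cid, sum)
  side_maj <- tapply(regions$side[sel], cid, function(v) {
    if (sum(v == 1L) >= sum(v == 2L)) "left" else "right"
  })
  group_maj <- tapply(regions$group[sel], cid, function(v) {
    if (sum(v == 1L) > sum(v == 2L)) "upper" else "lower"
  })
  cz <- tapply(mm[, 1], cid, mean)
  cy <- tapply(mm[, 2], cid, mean)
  cx <- tapply(mm[, 3], cid, mean)
  n_cells <- length(uk)
  denom <- pmax(as.numeric(n_par), 1)
  cells <- tibble::tibble(
    cell = seq_len(n_cells),
    ci = uk %/% 1e6, cj = (uk %% 1e6) %/% 1e3, ck = uk %% 1e3,
    centroid_z = as.numeric(cz), centroid_y = as.numeric(cy),
    centroid_x = as.numeric(cx),
    side = as.character(side_maj), group = as.character(group_maj),
    n_parenchyma = as.integer(n_par),
    severity = as.numeric(sev),
    frac_emphysema = as.numeric(n_emph) / denom,
    frac_fsad = as.numeric(n_fsad) / denom,
    frac_normal = as.numeric(n_norm) / denom
  )
  cells$severity[cells$n_parenchyma == 0] <- 0
  cells <- dplyr::arrange(cells, .data$severity)
  cells$rank <- seq_len(nrow(cells))
  cell_map <- array(0L, d)
  cell_map[sel] <- match(key, uk)
  # remap cell ids to severity rank order for a stable export
  id_to_rank <- integer(n_cells)
  id_to_rank[cells$cell] <- cells$rank
  cell_map[sel] <- id_to_rank[cell_map[sel]]
  cells$cell <- cells$rank
  total <- sum(cells$severity)
  structure(list(cells = cells, cell_size = cell_size, anchor = anchor,
                 intercept = model$intercept,
                 whole_lung_prediction = model$intercept + total),
            class = "bprm_grid", cell_map = cell_map)
}

#' @export
print.bprm_grid <- function(x, ...) {
  cat(sprintf("<bprm_grid> %d cells of %.0f mm; predicted FEV1/FVC%% %.2f (intercept %.2f)\n",
              nrow(x$cells), x$cell_size, x$whole_lung_prediction, x$intercept))
  invisible(x)
}

#' @export
tidy.bprm_grid <- function(x, ...) x$cells

#' @export
glance.bprm_grid <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells), cell_size = x$cell_size,
                 total_severity = sum(x$cells$severity),
                 intercept = x$intercept,
                 whole_lung_prediction = x$whole_lung_prediction)
}

#' Export the BPRM as NIfTI and CSV
#'
#' Writes a float severity map (each voxel painted with its cell's severity)
#' and the ranked cell table (most severe first).
#'
#' @param grid a [aggregate_grid()] result.
#' @param geometry the subject's inspiratory [volume3d].
#' @param path_nifti,path_csv output paths (`NULL` skips either).
#' @return Named list of written paths, invisibly.
#' @export
export_bprm <- function(grid, geometry, path_nifti = NULL, path_csv = NULL) {
  cell_map <- attr(grid, "cell_map")
  assert_that(all(dim(cell_map) == dim(geometry$values)),
              "geometry error: grid and volume dimensions differ")
  out <- list()
  if (!is.null(path_nifti)) {
    sev_lut <- c(0, grid$cells$severity[order(grid$cells$cell)])
    sev_map <- array(sev_lut[cell_map + 1L], dim(cell_map))
    write_volume(sev_map, path_nifti, geometry = geometry, datatype = "float")
    out$nifti <- path_nifti
  }
  if (!is.null(path_csv)) {
    utils::write.csv(as.data.frame(grid$cells), path_csv, row.names = FALSE)
    out$csv <- path_csv
  }
  invisible(out)
}

#' Plot a BPRM grid as axial severity tiles
#'
#' Diverging palette with the most severe (most negative) cells in blue.
#'
#' @param object a `bprm_grid`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bprm_grid <- function(object, ...) {
  df <- object$cells
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                                   fill = .data$severity)) +
    ggplot2::geom_tile(width = object$cell_size, height = object$cell_size) +
    ggplot2::facet_wrap(~round(.data$centroid_z)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "severity\n(FEV1/FVC%)",
                  title = "Bullous parametric response map")
}
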