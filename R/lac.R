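# Low attenuation cluster (LAC) extraction: iterative-erosion depth maps,
# bulla-core splitting by descending-depth (watershed) assignment, per-cluster
# low attenuation density (LAD), and emphysema-predominance classification of
# expiratory clusters.

#' Erosion depth map
#'
#' `depth(v)` is the number of iterative erosions (3^3 structuring element) a
#' lesion voxel survives: boundary voxels have depth 0, deeper voxels
#' accumulate the erosion count; background is −1. Iteration runs until the
#' mask is empty.
#'
#' @param lesion logical lesion mask (nonempty).
#' @return Integer array of erosion depths.
#' @export
erosion_depth_map <- function(lesion) {
  assert_that(sum(lesion) > 0, "lesion mask is empty")
  d <- dim(lesion)
  array(.erosion_depth_cpp(as.logical(lesion), as.integer(d)), dim = d)
}


#' Extract low attenuation clusters with bulla-core splitting
#'
#' Cores — the erosion survivors that contain the depth local maxima — are
#' the connected components of `{depth >= min_core_depth}`; every lesion
#' voxel is then assigned to exactly one core by descending-depth region
#' growth (marker-based watershed on the negated depth), so two bullae joined
#' by a neck thinner than the core depth separate while a single solid
#' cluster stays whole. Connected components without a qualifying core remain
#' single clusters. `min_core_depth = Inf` therefore degenerates to plain
#' connected-component labelling.
#'
#' @param lesion logical lesion mask.
#' @param depth erosion depth map from [erosion_depth_map()] (computed if
#'   `NULL`).
#' @param min_core_depth minimum plateau depth for a splitting core
#'   (default 2, so single-voxel noise never splits a cluster).
#' @param connectivity 6 or 26.
#' @param parenchyma_count denominator for LAD fractions.
#' @param geometry a [volume3d] for centroid coordinates (voxel units used if
#'   `NULL`).
#' @param phase,threshold provenance recorded on each record.
#' @param min_voxels clusters below this size are kept but flagged `small`.
#' @return A tibble with one row per LAC: `id`, `phase`, `threshold`,
#'   `voxel_count`, `lad` (fraction of parenchyma), `max_erosion_depth`,
#'   centroid (mm), `small`; label array attached as attribute `labels`,
#'   the denominator as `parenchyma_count`. The rows partition the lesion
#'   mask, so `sum(lad) == LAV%/100` exactly.
#' @export
extract_lacs <- function(lesion, depth = NULL, min_core_depth = 2,
                         connectivity = 26, parenchyma_count = sum(lesion),
                         geometry = NULL, phase = "inspiratory",
                         threshold = NA_real_, min_voxels = 8) {
  assert_that(connectivity %in% c(6, 26),
              "parameter error: connectivity must be 6 or 26")
  d <- dim(lesion)
  empty <- tibble::tibble(
    id = integer(0), phase = character(0), threshold = numeric(0),
    voxel_count = integer(0), lad = numeric(0), max_erosion_depth = integer(0),
    centroid_z = numeric(0), centroid_y = numeric(0), centroid_x = numeric(0),
    small = logical(0))
  if (sum(lesion) == 0) {
    attr(empty, "labels") <- array(0L, d)
    attr(empty, "parenchyma_count") <- parenchyma_count
    return(empty)
  }
  if (is.null(depth)) depth <- erosion_depth_map(lesion)
  comps <- label_components(lesion, connectivity)
  if (is.finite(min_core_depth)) {
    cores <- label_components(lesion & depth >= min_core_depth, connectivity)
    labels <- array(.watershed_desc_cpp(as.integer(depth), as.integer(cores),
                                        as.logical(lesion), as.integer(d),
                                        as.integer(connectivity)), dim = d)
  } else {
    labels <- array(0L, d)
  }
  # components without a qualifying core stay whole, with fresh ids
  n_core <- max(labels, 0L)
  unassigned <- lesion & labels == 0L
  if (any(unassigned)) {
    rest <- comps
    rest[!unassigned] <- 0L
    rest_ids <- sort(unique(rest[rest > 0L]))
    labels[unassigned] <- n_core + match(rest[unassigned], rest_ids)
  }
  ids <- sort(unique(labels[labels > 0L]))
  sel <- which(labels > 0L)
  lab_v <- labels[sel]
  vox <- arrayInd(sel, d)
  spacing <- if (is.null(geometry)) c(1, 1, 1) else geometry$spacing
  origin <- if (is.null(geometry)) c(0, 0, 0) else geometry$origin
  cnt <- tabulate(lab_v, nbins = max(ids))
  maxdep <- vapply(split(depth[sel], lab_v), max, integer(1))
  cz <- vapply(split((vox[, 1] - 1) * spacing[1] + origin[1], lab_v), mean, numeric(1))
  cy <- vapply(split((vox[, 2] - 1) * spacing[2] + origin[2], lab_v), mean, numeric(1))
  cx <- vapply(split((vox[, 3] - 1) * spacing[3] + origin[3], lab_v), mean, numeric(1))
  out <- tibble::tibble(
    id = ids,
    phase = phase,
    threshold = threshold,
    voxel_count = cnt[ids],
    lad = cnt[ids] / parenchyma_count,
    max_erosion_depth = as.integer(maxdep[as.character(ids)]),
    centroid_z = as.numeric(cz[as.character(ids)]),
    centroid_y = as.numeric(cy[as.character(ids)]),
    centroid_x = as.numeric(cx[as.character(ids)]),
    small = cnt[ids] < min_voxels
  )
  attr(out, "labels") <- labels
  attr(out, "parenchyma_count") <- parenchyma_count
  out
}

#' Classify expiratory LACs by emphysema predominance
#'
#' For each cluster of the expiratory air-trapping mask, the fraction of PRM
#' emphysema voxels decides the class: above `ratio_cut` the cluster is
#' emphysema-predominant (and excluded from the fSAD predictors); otherwise
#' it is an fSAD cluster whose effective LAD uses its PRM fSAD voxel count
#' rather than the full cluster size.
#'
#' @param lacs a [extract_lacs()] tibble from the expiratory −856 mask (the
#'   `labels` attribute is required).
#' @param prm a [prm_classify()] result on the same grid.
#' @param ratio_cut predominance cut (default 0.5 — majority).
#' @return The tibble with `lac_class` (`"emph_predominant"` or `"fsad"`),
#'   `fsad_voxels` and `lad_eff` (effective LAD) columns added.
#' @export
classify_lac_predominance <- function(lacs, prm, ratio_cut = 0.5) {
  assert_that(nrow(lacs) == 0 || all(lacs$phase == "expiratory"),
              "phase error: predominance applies to expiratory clusters")
  labels <- attr(lacs, "labels")
  assert_that(!is.null(labels), "lacs must carry their label map")
  pc <- attr(lacs, "parenchyma_count")
  if (nrow(lacs) == 0) {
    out <- dplyr::mutate(lacs, lac_class = character(0),
                         fsad_voxels = integer(0), lad_eff = numeric(0))
    attr(out, "labels") <- labels
    attr(out, "parenchyma_count") <- pc
    return(out)
  }
  nb <- max(lacs$id)
  n_emph <- tabulate(labels[prm$class == 3L & labels > 0L], nbins = nb)
  n_fsad <- tabulate(labels[prm$class == 2L & labels > 0L], nbins = nb)
  emph_frac <- n_emph[lacs$id] / lacs$voxel_count
  out <- dplyr::mutate(
    lacs,
    lac_class = ifelse(emph_frac > ratio_cut, "emph_predominant", "fsad"),
    fsad_voxels = n_fsad[.data$id],
    lad_eff = ifelse(emph_frac > ratio_cut, .data$lad, .data$fsad_voxels / pc)
  )
  attr(out, "labels") <- labels
  attr(out, "parenchyma_count") <- pc
  out
}

#' Assign side and lobe group to LACs
#'
#' Each cluster takes the (side, group) of the majority of its voxels; a
#' 50/50 group tie goes to `lower` (and a side tie to `left`).
#'
#' @param lacs an [extract_lacs()] tibble (with `labels` attribute).
#' @param regions a [region_mask] covering the lesion voxels.
#' @return The tibble with `side` and `group` columns filled.
#' @export
assign_regions <- function(lacs, regions) {
  labels <- attr(lacs, "labels")
  assert_that(!is.null(labels), "lacs must carry their label map")
  if (nrow(lacs) == 0) {
    out <- dplyr::mutate(lacs, side = character(0), group = character(0))
    attr(out, "labels") <- labels
    attr(out, "parenchyma_count") <- attr(lacs, "parenchyma_count")
    return(out)
  }
  nb <- max(lacs$id)
  vote <- function(mask) tabulate(labels[mask & labels > 0L], nbins = nb)
  n_left <- vote(regions$side == 1L)
  n_right <- vote(regions$side == 2L)
  n_up <- vote(regions$group == 1L)
  n_low <- vote(regions$group == 2L)
  out <- dplyr::mutate(
    lacs,
    side = ifelse(n_left[.data$id] >= n_right[.data$id], "left", "right"),
    group = ifelse(n_up[.data$id] > n_low[.data$id], "upper", "lower")
  )
  attr(out, "labels") <- labels
  attr(out, "parenchyma_count") <- attr(lacs, "parenchyma_count")
  out
}

#' Write a LAC table as CSV
#'
#' @param lacs a LAC tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lac_csv <- function(lacs, path) {
  utils::write.csv(as.data.frame(lacs), path, row.names = FALSE)
  invisible(path)
}
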