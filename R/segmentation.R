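# Lung/airway segmentation and left-right splitting. All component labelling
# uses 26-connectivity by default (configurable to 6).

mask_count <- function(m) sum(m)

erode_mask <- function(mask, iterations = 1, connectivity = 26) {
  d <- dim(mask)
  m <- as.logical(mask)
  for (i in seq_len(iterations)) m <- .erode_cpp(m, as.integer(d), connectivity)
  array(m, dim = d)
}

dilate_mask <- function(mask, iterations = 1, connectivity = 26) {
  d <- dim(mask)
  m <- as.logical(mask)
  for (i in seq_len(iterations)) m <- .dilate_cpp(m, as.integer(d), connectivity)
  array(m, dim = d)
}

close_mask <- function(mask, iterations = 1, connectivity = 26) {
  erode_mask(dilate_mask(mask, iterations, connectivity), iterations, connectivity)
}

label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  array(.cc_label_cpp(as.logical(mask), as.integer(d), connectivity), dim = d)
}

# fill cavities: background components not touching the image border
fill_holes <- function(mask, connectivity = 6) {
  d <- dim(mask)
  bg <- label_components(!mask, connectivity)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- unique(bg[border & !mask])
  hole <- !mask & !(bg %in% outside)
  mask | array(hole, d)
}

#' Locate a trachea seed voxel
#'
#' Deterministically picks an air-dense voxel (HU < −950) in the superior
#' quarter of the volume, centrally located in (y, x) — the trachea lumen.
#'
#' @param vol a [volume3d].
#' @return Integer voxel index triple (i, j, k), 1-based.
#' @export
find_trachea_seed <- function(vol) {
  d <- dim(vol$values)
  ctr_j <- (1 + d[2]) / 2; ctr_k <- (1 + d[3]) / 2
  # walk down from the top: the trachea is an enclosed air component (not
  # connected to the slice border, unlike exterior air), centrally located
  for (i in rev(seq(ceiling(0.5 * d[1]), d[1]))) {
    slc <- array(vol$values[i, , ], dim = c(1, d[2], d[3]))
    air <- slc < -950
    if (!any(air)) next
    lab <- label_components(air, 26)
    border_ids <- unique(c(lab[1, c(1, d[2]), ], lab[1, , c(1, d[3])]))
    ok_ids <- setdiff(unique(lab[lab > 0]), border_ids)
    if (length(ok_ids) == 0) next
    best <- NULL; best_d <- Inf
    for (id in ok_ids) {
      sel <- which(lab == id, arr.ind = TRUE)
      n <- nrow(sel)
      if (n < 5 || n > 0.05 * d[2] * d[3]) next
      cj <- mean(sel[, 2]); ck <- mean(sel[, 3])
      dd <- (cj - ctr_j)^2 + (ck - ctr_k)^2
      if (dd > (0.25 * d[2])^2 + (0.25 * d[3])^2) next
      if (dd < best_d) {
        pick <- sel[which.min((sel[, 2] - cj)^2 + (sel[, 3] - ck)^2), ]
        best <- c(i, pick[2], pick[3])
        best_d <- dd
      }
    }
    if (!is.null(best)) return(as.integer(best))
  }
  stop("no trachea candidate found", call. = FALSE)
}

#' Segment the airway by leak-guarded threshold region growing
#'
#' Grows a connected component from a trachea seed at successively more
#' permissive HU thresholds; a threshold step is rejected (and growing stops)
#' if the component volume jumps by more than `leak_factor` or exceeds
#' `max_fraction` of the volume — the leak guard that makes seeded growing
#' "adaptive".
#'
#' @param vol a [volume3d].
#' @param seed_point 1-based voxel index triple inside the trachea
#'   (HU < −900), e.g. from [find_trachea_seed()].
#' @param hu_start,hu_stop,hu_step threshold schedule (HU).
#' @param leak_factor maximum allowed volume ratio between consecutive steps.
#' @param max_fraction maximum airway fraction of the image volume.
#' @param connectivity 6 or 26.
#' @return Logical 3-D airway mask.
#' @export
segment_airway <- function(vol, seed_point, hu_start = -950, hu_stop = -870,
                           hu_step = 10, leak_factor = 3, max_fraction = 0.05,
                           connectivity = 26) {
  d <- dim(vol$values)
  seed_point <- as.integer(seed_point)
  hu_seed <- vol$values[seed_point[1], seed_point[2], seed_point[3]]
  assert_that(hu_seed < -900,
              sprintf("seed error: seed HU %.0f is not air-dense (< -900 required)", hu_seed))
  seed_lin <- as.integer((seed_point[1] - 1) + d[1] * ((seed_point[2] - 1) + d[2] * (seed_point[3] - 1)))
  thresholds <- seq(hu_start, hu_stop, by = hu_step)
  best <- NULL
  prev_n <- 0
  for (th in thresholds) {
    include <- as.logical(vol$values < th)
    grown <- .grow_from_seeds_cpp(include, seed_lin, as.integer(d), connectivity)
    n <- sum(grown)
    if (n == 0) next
    if (n > max_fraction * prod(d)) break
    if (prev_n > 0 && n > leak_factor * prev_n) break
    best <- grown
    prev_n <- n
  }
  assert_that(!is.null(best), "seed error: airway growth produced no voxels")
  array(best, dim = d)
}

#' Segment the lungs by seeded region growing
#'
#' Grows from airway-adjacent voxels under `upper_bound_hu`, re-includes
#' enclosed vascular structures by morphological closing and hole filling, and
#' finally subtracts the airway.
#'
#' @param vol a [volume3d].
#' @param airway logical airway mask (nonempty) from [segment_airway()].
#' @param upper_bound_hu growth upper bound; the default −200 HU keeps the
#'   seeded growth inside air-filled tissue (the literal +200 of lung-window
#'   conventions would flood soft tissue from an air seed).
#' @param closing_iter iterations of morphological closing for vessel
#'   re-inclusion (0 disables).
#' @param connectivity 6 or 26.
#' @return Logical 3-D lung mask (airway excluded).
#' @export
segment_lungs <- function(vol, airway, upper_bound_hu = -200, closing_iter = 2,
                          connectivity = 26) {
  d <- dim(vol$values)
  assert_that(sum(airway) > 0, "airway mask is empty")
  include <- as.logical(vol$values < upper_bound_hu)
  seed_band <- dilate_mask(airway, 1, connectivity) & !airway
  seeds <- which(as.logical(seed_band) & include) - 1L
  if (length(seeds) == 0) return(array(FALSE, d))
  grown <- array(.grow_from_seeds_cpp(include, as.integer(seeds), as.integer(d),
                                      connectivity), dim = d)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  if (sum(grown & border) >= 0.5 * sum(border))
    stop("leak error: grown region touches most of the image border; ",
         "upper_bound_hu too permissive", call. = FALSE)
  m <- grown
  if (closing_iter > 0) {
    # vessel re-inclusion: closing plus cavity filling (disabled together)
    m <- close_mask(m, closing_iter, connectivity)
    m <- fill_holes(m)
  }
  m & !airway
}

#' Split a lung mask into left and right
#'
#' Erodes until the mask separates into at least two components, keeps the two
#' largest as seeds, reassigns every original lung voxel to the nearest seed
#' by geodesic distance inside the mask (voxels in pockets unreachable from
#' either seed fall back to the Euclidean-nearest seed centroid), and labels
#' sides by centroid x-coordinate (larger x = patient left, RAS convention).
#'
#' @param lung logical lung mask with at least one component.
#' @param connectivity 6 or 26.
#' @param max_erosions abort limit.
#' @return Integer array: 0 outside, 1 left, 2 right. The number of erosions
#'   used is attached as attribute `erosions`.
#' @export
split_left_right <- function(lung, connectivity = 26, max_erosions = 50) {
  d <- dim(lung)
  assert_that(sum(lung) > 0, "lung mask is empty")
  cur <- lung
  n_er <- 0
  repeat {
    lab <- label_components(cur, connectivity)
    ncomp <- max(lab)
    if (ncomp >= 2) break
    cur <- erode_mask(cur, 1, connectivity)
    n_er <- n_er + 1
    if (sum(cur) == 0 || n_er > max_erosions)
      stop("split error: erosion exhausted the mask before it separated",
           call. = FALSE)
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[1:2]
  seed_lab <- array(0L, d)
  seed_lab[lab == keep[1]] <- 1L
  seed_lab[lab == keep[2]] <- 2L
  assigned <- array(.geodesic_label_cpp(as.logical(lung), as.integer(seed_lab),
                                        as.integer(d), connectivity), dim = d)
  left_over <- lung & assigned == 0L
  if (any(left_over)) {
    grids <- index_grids(d)
    cent <- lapply(1:2, function(s) {
      sel <- seed_lab == s
      c(mean(grids$i[sel]), mean(grids$j[sel]), mean(grids$k[sel]))
    })
    sel <- which(left_over)
    d1 <- (grids$i[sel] - cent[[1]][1])^2 + (grids$j[sel] - cent[[1]][2])^2 +
      (grids$k[sel] - cent[[1]][3])^2
    d2 <- (grids$i[sel] - cent[[2]][1])^2 + (grids$j[sel] - cent[[2]][2])^2 +
      (grids$k[sel] - cent[[2]][3])^2
    assigned[sel] <- ifelse(d1 <= d2, 1L, 2L)
  }
  # relabel so that 1 = left (larger x centroid), 2 = right
  grids_k <- index_grids(d)$k
  x1 <- mean(grids_k[assigned == 1L])
  x2 <- mean(grids_k[assigned == 2L])
  out <- array(0L, d)
  if (x1 >= x2) {
    out[assigned == 1L] <- 1L; out[assigned == 2L] <- 2L
  } else {
    out[assigned == 1L] <- 2L; out[assigned == 2L] <- 1L
  }
  attr(out, "erosions") <- n_er
  out
}

#' Region mask container
#'
#' Bundles per-voxel side labels (0 outside, 1 left, 2 right), lobe-group
#' labels (0 none, 1 upper, 2 lower) and the airway flag. Group labels are
#' only nonzero where side is nonzero; parenchyma (the denominator of every
#' density measure) is `side > 0` and not airway.
#'
#' @param side,group integer arrays; `airway` logical array.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(side, group, airway) {
  assert_that(all(group[side == 0L] == 0L),
              "group labels must be zero outside the lung")
  structure(list(side = side, group = group, airway = airway),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> lung voxels: %d (left %d / right %d), upper %d / lower %d, airway %d\n",
              sum(x$side > 0), sum(x$side == 1), sum(x$side == 2),
              sum(x$group == 1), sum(x$group == 2), sum(x$airway)))
  invisible(x)
}

#' Parenchyma mask of a region mask
#'
#' Lung voxels minus the airway — the denominator of every density measure.
#'
#' @param regions a [region_mask].
#' @return Logical array.
#' @export
parenchyma_mask <- function(regions) {
  regions$side > 0L & !regions$airway
}

#' Full segmentation of one CT phase
#'
#' Airway growing, lung growing, left/right splitting, fissure detection and
#' upper/lower lobe-group partition, assembled into a [region_mask].
#'
#' @param vol a [volume3d].
#' @param config a [pipeline_config()] list (segmentation parameters used).
#' @return A [region_mask].
#' @export
segment_subject <- function(vol, config = pipeline_config()) {
  sc <- config$segmentation
  seed <- find_trachea_seed(vol)
  airway <- segment_airway(vol, seed,
                           leak_factor = sc$leak_factor,
                           connectivity = sc$connectivity)
  lung <- segment_lungs(vol, airway, upper_bound_hu = sc$upper_bound_hu,
                        closing_iter = sc$closing_iter,
                        connectivity = sc$connectivity)
  side <- split_left_right(lung, connectivity = sc$connectivity)
  group <- array(0L, dim(side))
  smoothed <- gaussian_smooth(vol$values, vol$spacing, sc$fissure_sigma_mm)
  for (s in 1:2) {
    side_mask <- side == s
    pts <- detect_fissure_points(vol, side_mask, smoothed = smoothed,
                                 threshold = sc$fissure_threshold)
    group_s <- fit_lobe_surface(pts, side_mask, vol,
                                fallback_height = sc$fallback_height)
    group[side_mask] <- group_s[side_mask]
  }
  region_mask(side = side, group = group, airway = airway)
}
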