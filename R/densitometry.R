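# Threshold densitometry and PRM classification on the co-registered pair.
# All percentages use one denominator: whole-lung parenchyma voxels (lung
# minus airway, restricted to the co-registration validity region when a
# warped volume is involved), so regional values add up to whole-lung values.

#' Densitometric HU thresholds
#'
#' Mild emphysema at −920 HU (inspiratory), severe emphysema at −950 HU
#' (inspiratory), air-trapping at −856 HU (expiratory). `emph_rule` selects
#' the PRM emphysema definition: `"paper_both_950"` (default) requires
#' HU < −950 on both the inspiratory and the co-registered expiratory volume;
#' `"classic_prm"` uses inspiratory < −950 with expiratory < −856.
#'
#' @param emph_mild,emph_severe,air_trap HU cut points
#'   (`emph_severe < emph_mild < air_trap < 0`). Set `emph_mild = -930` for
#'   the alternative mild-emphysema cut.
#' @param emph_rule PRM emphysema rule.
#' @return A list of class `thresholds`.
#' @export
thresholds <- function(emph_mild = -920, emph_severe = -950, air_trap = -856,
                       emph_rule = c("paper_both_950", "classic_prm")) {
  emph_rule <- match.arg(emph_rule)
  assert_that(emph_severe < emph_mild && emph_mild < air_trap && air_trap < 0,
              "require emph_severe < emph_mild < air_trap < 0")
  structure(list(emph_mild = emph_mild, emph_severe = emph_severe,
                 air_trap = air_trap, emph_rule = emph_rule),
            class = "thresholds")
}

#' Binarize a volume under an HU threshold
#'
#' Strict inequality everywhere: a voxel is a lesion voxel iff it lies in the
#' parenchyma mask and its HU is strictly below `threshold`.
#'
#' @param vol a [volume3d].
#' @param parenchyma logical parenchyma mask.
#' @param threshold HU cut point.
#' @return Logical lesion mask.
#' @export
binarize <- function(vol, parenchyma, threshold) {
  assert_that(threshold >= -1024 && threshold <= 3071,
              "threshold outside the HU range")
  parenchyma & vol$values < threshold
}

#' Low attenuation volume percentage
#'
#' `100 * |lesion ∩ parenchyma| / |parenchyma|`. With `regions` given, also
#' reports per-side and per-lobe-group rows — regional lesion counts over the
#' same whole-lung denominator, so regions add up to the whole.
#'
#' @param lesion logical lesion mask.
#' @param parenchyma logical parenchyma mask (nonempty).
#' @param regions optional [region_mask] for regional rows.
#' @return A single percentage, or a tibble (`region`, `lav_pct`) when
#'   `regions` is supplied.
#' @export
lav_percent <- function(lesion, parenchyma, regions = NULL) {
  denom <- sum(parenchyma)
  assert_that(denom > 0, "division error: empty parenchyma")
  les <- lesion & parenchyma
  if (is.null(regions)) return(100 * sum(les) / denom)
  rows <- list(
    whole = TRUE,
    upper = regions$group == 1L,
    lower = regions$group == 2L,
    left = regions$side == 1L,
    right = regions$side == 2L
  )
  tibble::tibble(
    region = names(rows),
    lav_pct = vapply(rows, function(m) 100 * sum(les & m) / denom, numeric(1))
  )
}

#' PRM voxel classification
#'
#' Classifies each effective-parenchyma voxel of the co-registered pair as
#' normal, fSAD or emphysema. Under the default rule emphysema requires
#' HU < −950 on both volumes and fSAD is expiratory HU < −856 excluding
#' emphysema voxels; under `classic_prm` emphysema is inspiratory < −950 with
#' expiratory < −856 and fSAD requires inspiratory ≥ −950. Voxels outside the
#' warp validity region are classified `outside` and excluded from all
#' counts.
#'
#' @param insp inspiratory [volume3d].
#' @param coreg_exp co-registered expiratory [volume3d] on the same grid
#'   (e.g. from [warp_volume()]; its `valid` attribute is honoured).
#' @param parenchyma logical parenchyma mask.
#' @param th a [thresholds()] list.
#' @param regions optional [region_mask]; adds per-region class counts.
#' @return Object of class `prm_map`: `class` array (0 outside, 1 normal,
#'   2 fSAD, 3 emphysema), `counts` tibble, `parenchyma` (the effective
#'   parenchyma mask used), and the thresholds.
#' @export
prm_classify <- function(insp, coreg_exp, parenchyma, th = thresholds(),
                         regions = NULL) {
  assert_that(all(dim(insp$values) == dim(coreg_exp$values)),
              "geometry error: volumes are on different grids")
  valid <- attr(coreg_exp, "valid") %||% array(TRUE, dim(insp$values))
  par_eff <- parenchyma & valid
  iv <- insp$values
  ev <- coreg_exp$values
  cls <- array(0L, dim(iv))
  if (th$emph_rule == "paper_both_950") {
    emph <- iv < th$emph_severe & ev < th$emph_severe
    fsad <- ev < th$air_trap & !emph
  } else {
    emph <- iv < th$emph_severe & ev < th$air_trap
    fsad <- iv >= th$emph_severe & ev < th$air_trap
  }
  cls[par_eff] <- 1L
  cls[par_eff & fsad] <- 2L
  cls[par_eff & emph] <- 3L
  counts <- tibble::tibble(
    class = c("normal", "fSAD", "emphysema"),
    n = c(sum(cls == 1L), sum(cls == 2L), sum(cls == 3L))
  )
  if (!is.null(regions)) {
    reg <- expand.grid(side = c("left", "right"), group = c("upper", "lower"),
                       stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(reg)), function(r) {
      m <- regions$side == match(reg$side[r], c("left", "right")) &
        regions$group == match(reg$group[r], c("upper", "lower"))
      tibble::tibble(side = reg$side[r], group = reg$group[r],
                     class = c("normal", "fSAD", "emphysema"),
                     n = c(sum(cls == 1L & m), sum(cls == 2L & m),
                           sum(cls == 3L & m)))
    })
    counts <- list(global = counts, regional = dplyr::bind_rows(rows))
  }
  structure(list(class = cls, counts = counts, parenchyma = par_eff,
                 thresholds = th),
            class = "prm_map")
}

#' @export
print.prm_map <- function(x, ...) {
  n <- sum(x$parenchyma)
  cat(sprintf("<prm_map> parenchyma %d voxels: normal %.1f%%, fSAD %.1f%%, emphysema %.1f%% (%s)\n",
              n, 100 * sum(x$class == 1L) / n, 100 * sum(x$class == 2L) / n,
              100 * sum(x$class == 3L) / n, x$thresholds$emph_rule))
  invisible(x)
}

#' Composite LAV% table
#'
#' Threshold-based and PRM-based low attenuation percentages per region:
#' mild/severe emphysema (inspiratory −920 / −950), air-trapping (expiratory
#' −856), PRM fSAD, and the composite sums Emph920+AirT and Emph950+fSAD
#' (PRM classification guarantees the Emph950 and fSAD masks are disjoint, so
#' the composite is a plain addition).
#'
#' @param prm a [prm_classify()] result.
#' @param insp inspiratory [volume3d].
#' @param coreg_exp co-registered expiratory [volume3d].
#' @param regions a [region_mask].
#' @return A tibble with one row per region (`whole`, `upper`, `lower`,
#'   `left`, `right`) and one column per measure.
#' @export
composite_lav <- function(prm, insp, coreg_exp, regions) {
  th <- prm$thresholds
  par_eff <- prm$parenchyma
  denom <- sum(par_eff)
  assert_that(denom > 0, "division error: empty parenchyma")
  masks <- list(
    emph920 = par_eff & insp$values < th$emph_mild,
    emph950 = par_eff & insp$values < th$emph_severe,
    airt = par_eff & coreg_exp$values < th$air_trap,
    fsad = prm$class == 2L
  )
  region_masks <- list(
    whole = array(TRUE, dim(par_eff)),
    upper = regions$group == 1L,
    lower = regions$group == 2L,
    left = regions$side == 1L,
    right = regions$side == 2L
  )
  out <- lapply(names(region_masks), function(rn) {
    rm <- region_masks[[rn]]
    v <- vapply(masks, function(m) 100 * sum(m & rm) / denom, numeric(1))
    tibble::tibble(region = rn,
                   lav_emph920 = v[["emph920"]], lav_emph950 = v[["emph950"]],
                   lav_airt = v[["airt"]], lav_fsad = v[["fsad"]],
                   lav_emph920_airt = v[["emph920"]] + v[["airt"]],
                   lav_emph950_fsad = v[["emph950"]] + v[["fsad"]])
  })
  dplyr::bind_rows(out)
}
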