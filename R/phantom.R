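# Synthetic paired-CT phantom with known deformation and lesion truth.
# Geometry is analytic (ellipsoidal lungs in a soft-tissue torso, a Y-shaped
# airway, one oblique fissure plane per lung, spherical bullae / air-trapping
# regions); expiration is a known smooth contraction toward each hilum plus a
# low-frequency sinusoid. All randomness is driven by one seed through named
# streams, so adding lesions never perturbs the parenchyma noise field.

#' Default phantom HU statistics per tissue class and phase
#'
#' Means/SDs are chosen so that the densitometric thresholds (−950, −920,
#' −856 HU) separate classes with margins of at least ~3 SD.
#'
#' @return A list with `mean_insp`, `mean_exp`, `sd` named by tissue class.
#' @export
phantom_hu <- function() {
  classes <- c("air", "body", "parenchyma", "fissure", "vessel",
               "trap", "bulla", "airway")
  list(
    mean_insp = c(air = -1000, body = 40, parenchyma = -850, fissure = -300,
                  vessel = 30, trap = -900, bulla = -980, airway = -1000),
    mean_exp = c(air = -1000, body = 40, parenchyma = -760, fissure = -300,
                 vessel = 30, trap = -900, bulla = -980, airway = -1000),
    sd = c(air = 5, body = 10, parenchyma = 30, fissure = 10,
           vessel = 10, trap = 15, bulla = 10, airway = 5),
    classes = classes
  )
}

phantom_geometry <- function(shape, spacing) {
  extent <- (shape - 1) * spacing
  ctr <- extent / 2
  torso_semi <- extent * c(0.47, 0.42, 0.47)
  lung_semi <- extent * c(0.33, 0.23, 0.16)
  xoff <- 0.23 * extent[3]
  lungs <- list(
    right = list(center = c(ctr[1], ctr[2], ctr[3] - xoff), semi = lung_semi),
    left  = list(center = c(ctr[1], ctr[2], ctr[3] + xoff), semi = lung_semi)
  )
  for (s in names(lungs)) {
    med <- if (s == "right") 1 else -1
    lungs[[s]]$hilum <- lungs[[s]]$center + c(0, 0, med * 0.5 * lung_semi[3])
    # airway branch ends near the medial lung boundary, clear of the interior
    lungs[[s]]$hilum_airway <- lungs[[s]]$center + c(0, 0, med * 0.85 * lung_semi[3])
    # oblique fissure plane: z = cz + slope * (y - cy)
    lungs[[s]]$fissure_slope <- 0.35
  }
  carina <- c(ctr[1] + 0.12 * extent[1], ctr[2], ctr[3])
  # keep the capsule end (radius 3.5 mm) strictly inside the torso apex so
  # the trachea is never connected to exterior air
  trachea_top <- c(min(0.92 * extent[1], ctr[1] + torso_semi[1] - 6.5),
                   ctr[2], ctr[3])
  airway_segments <- list(
    list(a = trachea_top, b = carina, r = 3.5),
    list(a = carina, b = lungs$right$hilum_airway, r = 2.5),
    list(a = carina, b = lungs$left$hilum_airway, r = 2.5)
  )
  list(extent = extent, center = ctr, torso_semi = torso_semi,
       lungs = lungs, airway = airway_segments)
}

# normalized ellipsoid radius (<= 1 inside); pts n x 3 (z, y, x) mm
ellipsoid_rho <- function(pts, center, semi) {
  sqrt(((pts[, 1] - center[1]) / semi[1])^2 +
         ((pts[, 2] - center[2]) / semi[2])^2 +
         ((pts[, 3] - center[3]) / semi[3])^2)
}

# distance from points to a 3-D segment a-b
segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
         (pts[, 2] - (a[2] + t * ab[2]))^2 +
         (pts[, 3] - (a[3] + t * ab[3]))^2)
}

airway_distance <- function(pts, geom) {
  d <- rep(Inf, nrow(pts))
  for (seg in geom$airway) d <- pmin(d, segment_distance(pts, seg$a, seg$b) - seg$r)
  d
}

# tissue class per point; precedence airway > bulla > trap > vessel > fissure
# > parenchyma > body > air. catalog: data frame z, y, x, radius, class.
phantom_membership <- function(pts, geom, catalog) {
  n <- nrow(pts)
  cls <- rep("air", n)
  in_torso <- ellipsoid_rho(pts, geom$center, geom$torso_semi) <= 1
  cls[in_torso] <- "body"
  in_lung <- rep(FALSE, n)
  fis <- rep(FALSE, n)
  for (l in geom$lungs) {
    rho <- ellipsoid_rho(pts, l$center, l$semi)
    inl <- rho <= 1
    in_lung <- in_lung | inl
    f <- pts[, 1] - (l$center[1] + l$fissure_slope * (pts[, 2] - l$center[2]))
    fis <- fis | (inl & abs(f) <= 0.6)
  }
  cls[in_lung] <- "parenchyma"
  cls[fis] <- "fissure"
  if (!is.null(catalog) && nrow(catalog) > 0) {
    for (r in seq_len(nrow(catalog))) {
      ctr <- c(catalog$z[r], catalog$y[r], catalog$x[r])
      inside <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
                       (pts[, 3] - ctr[3])^2) <= catalog$radius[r]
      cls[inside & in_lung] <- catalog$class[r]
    }
  }
  cls[airway_distance(pts, geom) <= 0] <- "airway"
  cls
}

# forward displacement (mm) at inspiratory-space points: contraction toward
# each hilum plus a low-frequency sinusoid, weighted to vanish outside lungs
phantom_displacement <- function(pts, geom, contraction, sinus_amplitude,
                                 sinus_wavelength) {
  u <- matrix(0, nrow(pts), 3)
  for (l in geom$lungs) {
    rho <- ellipsoid_rho(pts, l$center, l$semi)
    w <- ifelse(rho <= 1, 1, exp(-((rho - 1) / 0.15)^2))
    keep <- w > 1e-4
    if (!any(keep)) next
    p <- pts[keep, , drop = FALSE]
    uc <- -contraction * sweep(p, 2, l$hilum, `-`)
    us <- cbind(sin(2 * pi * p[, 1] / sinus_wavelength),
                sin(2 * pi * p[, 2] / sinus_wavelength + 1),
                sin(2 * pi * p[, 3] / sinus_wavelength + 2)) * sinus_amplitude
    u[keep, ] <- u[keep, ] + w[keep] * (uc + us)
  }
  u
}

place_spheres <- function(geom, n, radius_range, existing, seed, stream,
                          max_tries = 20000) {
  if (n == 0) return(existing)
  with_stream_seed(seed, stream, {
    placed <- 0
    tries <- 0
    while (placed < n) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place lesions: phantom too small for the requested ",
             "count/radius", call. = FALSE)
      r <- runif(1, radius_range[1], radius_range[2])
      side <- sample(names(geom$lungs), 1)
      l <- geom$lungs[[side]]
      c0 <- l$center + (2 * runif(3) - 1) * l$semi
      p <- matrix(c0, 1, 3)
      # entirely inside the lung with a 2 mm margin (shrunken-axis check)
      semi_in <- pmax(l$semi - (r + 2), 0.5)
      if (ellipsoid_rho(p, l$center, semi_in) > 1) next
      if (airway_distance(p, geom) < r + 2) next
      # keep clear of the fissure plane and of other lesions
      f <- c0[1] - (l$center[1] + l$fissure_slope * (c0[2] - l$center[2]))
      if (abs(f) < r + 2) next
      if (!is.null(existing) && nrow(existing) > 0) {
        dd <- sqrt((existing$z - c0[1])^2 + (existing$y - c0[2])^2 +
                     (existing$x - c0[3])^2)
        if (any(dd < existing$radius + r + 2)) next
      }
      existing <- rbind(existing, data.frame(
        z = c0[1], y = c0[2], x = c0[3], radius = r,
        class = sub("s$", "", stream), lung = side))
      placed <- placed + 1
    }
    existing
  })
}

#' Generate a paired inspiratory/expiratory CT phantom with ground truth
#'
#' Builds two ellipsoidal lungs inside a soft-tissue torso, with a Y-shaped
#' airway (−1000 HU) reaching both lungs, one oblique fissure plane per lung,
#' small bright vessels, and spherical lesions: emphysema bullae
#' (~N(−980, 10) HU in both phases) and air-trapping regions (~N(−900, 15) HU
#' in both phases, so inspiratory HU ≥ −950 and expiratory HU < −856 in
#' expectation). The expiratory volume is the inspiratory geometry warped by a
#' known smooth contraction toward each hilum (default 8%) plus a 2 mm
#' low-frequency sinusoid.
#'
#' @param shape voxel triple (z, y, x), each at least 32.
#' @param spacing mm triple; anisotropy allowed.
#' @param n_bullae,n_traps lesion counts (>= 0).
#' @param seed integer master seed; identical seeds give bit-identical output.
#' @param contraction linear contraction fraction of expiration.
#' @param sinus_amplitude,sinus_wavelength sinusoidal perturbation (mm).
#' @param radius_range lesion radius range (mm), scalar or length 2.
#' @param hu HU statistics per class, see [phantom_hu()].
#' @return A list of class `phantom_pair` with elements `insp`, `exp`
#'   ([volume3d]s) and `truth`: `deformation` (list of 3 arrays, mm
#'   displacement inspiratory→expiratory on the inspiratory grid),
#'   `lesion_labels` (0 normal, 1 emphysema, 2 air-trap), `lung_truth`
#'   (per-phase binary masks, airway removed), `lobe_truth` (0/1/2 =
#'   outside/upper/lower), `side_truth` (0/1/2 = outside/left/right),
#'   `bulla_catalog` and the geometry.
#' @export
make_phantom_pair <- function(shape = c(96, 96, 96), spacing = c(1, 1, 1),
                              n_bullae = 3, n_traps = 3, seed = 1,
                              contraction = 0.08, sinus_amplitude = 2,
                              sinus_wavelength = 60, radius_range = c(5, 8),
                              hu = phantom_hu()) {
  shape <- as.integer(shape)
  if (length(radius_range) == 1) radius_range <- rep(radius_range, 2)
  assert_that(all(shape >= 32), "sizing error: shape must be at least 32 voxels per axis")
  assert_that(n_bullae >= 0 && n_traps >= 0, "lesion counts must be >= 0")
  geom <- phantom_geometry(shape, spacing)

  catalog <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                        radius = numeric(0), class = character(0),
                        lung = character(0))
  catalog <- place_spheres(geom, 2L, c(2.5, 2.5), catalog, seed, "vessels")
  catalog <- place_spheres(geom, n_bullae, radius_range, catalog, seed, "bullas")
  catalog <- place_spheres(geom, n_traps, radius_range, catalog, seed, "traps")
  catalog$class <- sub("^bulla.*", "bulla", catalog$class)

  grids <- index_grids(shape)
  pts <- cbind((as.numeric(grids$i) - 1) * spacing[1],
               (as.numeric(grids$j) - 1) * spacing[2],
               (as.numeric(grids$k) - 1) * spacing[3])

  cls_insp <- phantom_membership(pts, geom, catalog)
  z_insp <- with_stream_seed(seed, "noise-insp", rnorm(nrow(pts)))
  vals_insp <- hu$mean_insp[cls_insp] + hu$sd[cls_insp] * z_insp
  vals_insp <- pmin(pmax(vals_insp, -1024), 3071)
  insp <- volume3d(array(vals_insp, dim = shape), spacing, phase = "inspiratory")

  # expiratory grid: pull back through the forward map by fixed-point iteration
  src <- pts
  for (it in 1:4) {
    u <- phantom_displacement(src, geom, contraction, sinus_amplitude,
                              sinus_wavelength)
    src <- pts - u
  }
  cls_exp <- phantom_membership(src, geom, catalog)
  z_exp <- with_stream_seed(seed, "noise-exp", rnorm(nrow(pts)))
  vals_exp <- hu$mean_exp[cls_exp] + hu$sd[cls_exp] * z_exp
  vals_exp <- pmin(pmax(vals_exp, -1024), 3071)
  expv <- volume3d(array(vals_exp, dim = shape), spacing, phase = "expiratory")

  u_fwd <- phantom_displacement(pts, geom, contraction, sinus_amplitude,
                                sinus_wavelength)
  lesion_labels <- array(0L, dim = shape)
  lesion_labels[cls_insp == "bulla"] <- 1L
  lesion_labels[cls_insp == "trap"] <- 2L
  lesion_labels_exp <- array(0L, dim = shape)
  lesion_labels_exp[cls_exp == "bulla"] <- 1L
  lesion_labels_exp[cls_exp == "trap"] <- 2L

  lung_classes <- c("parenchyma", "fissure", "vessel", "trap", "bulla")
  lung_insp <- array(cls_insp %in% lung_classes, dim = shape)
  lung_exp <- array(cls_exp %in% lung_classes, dim = shape)

  side_truth <- array(0L, dim = shape)
  lobe_truth <- array(0L, dim = shape)
  for (s in names(geom$lungs)) {
    l <- geom$lungs[[s]]
    inl <- ellipsoid_rho(pts, l$center, l$semi) <= 1 & as.logical(lung_insp)
    side_truth[inl] <- if (s == "left") 1L else 2L
    f <- pts[, 1] - (l$center[1] + l$fissure_slope * (pts[, 2] - l$center[2]))
    lobe_truth[inl & f > 0] <- 1L  # upper = superior to the fissure surface
    lobe_truth[inl & f <= 0] <- 2L
  }

  truth <- list(
    deformation = list(dz = array(u_fwd[, 1], shape),
                       dy = array(u_fwd[, 2], shape),
                       dx = array(u_fwd[, 3], shape)),
    lesion_labels = lesion_labels,
    lesion_labels_exp = lesion_labels_exp,
    lung_truth = list(inspiratory = lung_insp, expiratory = lung_exp),
    side_truth = side_truth,
    lobe_truth = lobe_truth,
    bulla_catalog = tibble::as_tibble(
      catalog[catalog$class %in% c("bulla", "trap"), , drop = FALSE]),
    geometry = geom,
    params = list(shape = shape, spacing = spacing, seed = seed,
                  contraction = contraction,
                  sinus_amplitude = sinus_amplitude,
                  sinus_wavelength = sinus_wavelength)
  )
  structure(list(insp = insp, exp = expv, truth = truth),
            class = "phantom_pair")
}

#' Evaluate the phantom's true deformation at arbitrary points
#'
#' Maps inspiratory-space points (mm) to their expiratory-space positions
#' under the phantom's known forward field.
#'
#' @param truth the `truth` element of a [make_phantom_pair()] result.
#' @param pts_mm n x 3 matrix of (z, y, x) mm coordinates.
#' @return n x 3 matrix of deformed coordinates (mm).
#' @export
phantom_deform <- function(truth, pts_mm) {
  p <- truth$params
  u <- phantom_displacement(pts_mm, truth$geometry, p$contraction,
                            p$sinus_amplitude, p$sinus_wavelength)
  pts_mm + u
}

#' Write a phantom pair plus truth to disk
#'
#' Writes the two phases as NIfTI, the lesion/lobe/side truth as NIfTI label
#' maps, and the lesion catalog and parameters as a JSON sidecar.
#'
#' @param pair a [make_phantom_pair()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$insp, file.path(dir, "insp.nii.gz"), datatype = "float")
  write_volume(pair$exp, file.path(dir, "exp.nii.gz"), datatype = "float")
  g <- pair$insp
  write_volume(pair$truth$lesion_labels + 0, file.path(dir, "lesion_truth.nii.gz"),
               geometry = g, datatype = "uint8")
  write_volume((pair$truth$lung_truth$inspiratory) + 0,
               file.path(dir, "lung_truth_insp.nii.gz"), geometry = g,
               datatype = "uint8")
  write_volume(pair$truth$lobe_truth + 0, file.path(dir, "lobe_truth.nii.gz"),
               geometry = g, datatype = "uint8")
  jsonlite::write_json(
    list(bulla_catalog = pair$truth$bulla_catalog,
         params = pair$truth$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
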