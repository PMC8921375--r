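#' 3-D HU volume with physical geometry
#'
#' A light container for a CT phase: a 3-D array of Hounsfield units with
#' physical voxel spacing and origin. The fixed axis order is `(z, y, x)` —
#' the first array index runs cranio-caudally — and the physical coordinate of
#' voxel `(i, j, k)` (1-based) is `origin + (index - 1) * spacing`, per axis,
#' in millimetres.
#'
#' @param values 3-D numeric array of HU, axis order (z, y, x).
#' @param spacing positive mm triple (dz, dy, dx).
#' @param origin mm triple (z0, y0, x0); default zeros.
#' @param phase `"inspiratory"` or `"expiratory"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing, origin = c(0, 0, 0),
                     phase = c("inspiratory", "expiratory")) {
  phase <- match.arg(phase)
  assert_that(length(dim(values)) == 3, "values must be a 3-D array")
  assert_that(all(spacing > 0) && length(spacing) == 3,
              "spacing must be a strictly positive mm triple")
  rng <- range(values, na.rm = TRUE)
  assert_that(rng[1] >= -1024 - 1e-9 && rng[2] <= 3071 + 1e-9,
              "HU must lie within [-1024, 3071]")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), phase = phase),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s, dim (z,y,x) = %s, spacing mm = %s, HU [%.0f, %.0f]\n",
              x$phase, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

# physical coordinates (mm, columns z,y,x) of 1-based voxel indices (n x 3)
voxel_to_mm <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

mm_to_voxel <- function(vol, mm) {
  sweep(sweep(mm, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI (or any format RNifti reads) file, normalizes the in-memory
#' orientation to RAS, converts to the package's (z, y, x) axis order and
#' clamps HU to \[−1024, 3071\] (a warning reports how many voxels were
#' clamped).
#'
#' @param path file path.
#' @param phase CT phase label to attach.
#' @return A [volume3d].
#' @export
read_volume <- function(path, phase = c("inspiratory", "expiratory")) {
  phase <- match.arg(phase)
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error reading ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  RNifti::orientation(img) <- "RAS"
  a <- as.array(img)
  assert_that(length(dim(a)) == 3, "expected a 3-D volume")
  pix <- attr(img, "pixdim")[1:3] # (dx, dy, dz) after reorientation
  orig_xyz <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  vals <- aperm(a, c(3, 2, 1))
  n_clamped <- sum(vals < -1024 | vals > 3071)
  if (n_clamped > 0) {
    warning(sprintf("%d voxels clamped to [-1024, 3071]", n_clamped))
    vals <- pmin(pmax(vals, -1024), 3071)
    dim(vals) <- rev(dim(a))
  }
  volume3d(vals, spacing = rev(pix), origin = rev(orig_xyz), phase = phase)
}

#' Write a volume (or mask) as NIfTI
#'
#' @param vol a [volume3d], or a plain 3-D array (written as given, with
#'   `spacing`/`origin` taken from `geometry`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geometry optional [volume3d] providing spacing/origin for arrays.
#' @param datatype NIfTI datatype passed to RNifti (e.g. "int16", "float",
#'   "uint8").
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, geometry = NULL, datatype = "float") {
  if (is.array(vol)) {
    assert_that(!is.null(geometry), "arrays need a geometry volume")
    spacing <- geometry$spacing; origin <- geometry$origin
    values <- vol
  } else {
    spacing <- vol$spacing; origin <- vol$origin; values <- vol$values
  }
  a <- aperm(values, c(3, 2, 1)) # back to (x, y, z)
  storage.mode(a) <- "double"
  affine <- diag(4)
  affine[1, 1] <- spacing[3]; affine[2, 2] <- spacing[2]; affine[3, 3] <- spacing[1]
  affine[1:3, 4] <- rev(origin)
  attr(a, "pixdim") <- rev(spacing)
  img <- RNifti::asNifti(a, datatype = datatype)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Trilinear sampling of a 3-D array at continuous 1-based voxel coordinates
# (n x 3 matrix). Out-of-bounds rows return `fill`.
sample_trilinear <- function(values, pts, fill = NA_real_) {
  d <- dim(values)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
    pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  ok[is.na(ok)] <- FALSE
  # lower cell corner, clamped so the exact upper boundary stays in range
  i0 <- pmin(floor(pts[, 1]), d[1] - 1); fi <- pts[, 1] - i0
  j0 <- pmin(floor(pts[, 2]), d[2] - 1); fj <- pts[, 2] - j0
  k0 <- pmin(floor(pts[, 3]), d[3] - 1); fk <- pts[, 3] - k0
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  ix <- function(i, j, k) (i) + d[1] * ((j - 1) + d[2] * (k - 1))
  v <- values
  c000 <- v[ix(i0, j0, k0)];     c100 <- v[ix(i0 + 1, j0, k0)]
  c010 <- v[ix(i0, j0 + 1, k0)]; c110 <- v[ix(i0 + 1, j0 + 1, k0)]
  c001 <- v[ix(i0, j0, k0 + 1)]; c101 <- v[ix(i0 + 1, j0, k0 + 1)]
  c011 <- v[ix(i0, j0 + 1, k0 + 1)]; c111 <- v[ix(i0 + 1, j0 + 1, k0 + 1)]
  out[ok] <-
    c000 * (1 - fi) * (1 - fj) * (1 - fk) + c100 * fi * (1 - fj) * (1 - fk) +
    c010 * (1 - fi) * fj * (1 - fk) + c110 * fi * fj * (1 - fk) +
    c001 * (1 - fi) * (1 - fj) * fk + c101 * fi * (1 - fj) * fk +
    c011 * (1 - fi) * fj * fk + c111 * fi * fj * fk
  out
}

# Separable Gaussian smoothing; sigma in mm (scalar), spacing mm triple.
gaussian_smooth <- function(values, spacing, sigma_mm) {
  out <- values
  d <- dim(values)
  for (axis in 1:3) {
    sig_vox <- sigma_mm / spacing[axis]
    if (sig_vox < 1e-6) next
    half <- max(1L, ceiling(3 * sig_vox))
    k <- dnorm(seq(-half, half), sd = sig_vox)
    k <- k / sum(k)
    out <- array(.conv_axis_cpp(as.numeric(out), as.integer(d), k, axis - 1L),
                 dim = d)
  }
  out
}
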