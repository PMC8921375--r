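# Fissure detection by a Hessian plate filter and lobe-group partition by a
# regularized thin plate spline surface z = f(y, x).

# second derivatives of a smoothed volume by central differences (mm units)
hessian_components <- function(sm, spacing) {
  d2 <- function(axis) {
    (shift_array(sm, axis, 1) - 2 * sm + shift_array(sm, axis, -1)) /
      spacing[axis]^2
  }
  dcross <- function(a1, a2) {
    (shift_array(shift_array(sm, a1, 1), a2, 1) -
       shift_array(shift_array(sm, a1, 1), a2, -1) -
       shift_array(shift_array(sm, a1, -1), a2, 1) +
       shift_array(shift_array(sm, a1, -1), a2, -1)) /
      (4 * spacing[a1] * spacing[a2])
  }
  list(h11 = d2(1), h22 = d2(2), h33 = d2(3),
       h12 = dcross(1, 2), h13 = dcross(1, 3), h23 = dcross(2, 3))
}

# eigenvalues of symmetric 3x3 matrices, vectorized (trigonometric method);
# returns a list sorted by |lambda| descending
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- ifelse(p < 1e-12, 1, p)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p; b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  degen <- p < 1e-12
  e1[degen] <- q[degen]; e2[degen] <- q[degen]; e3[degen] <- q[degen]
  # sort by absolute value, descending
  m <- cbind(e1, e2, e3)
  am <- abs(m)
  o1 <- max.col(am, ties.method = "first")
  l1 <- m[cbind(seq_len(nrow(m)), o1)]
  am[cbind(seq_len(nrow(m)), o1)] <- -Inf
  o2 <- max.col(am, ties.method = "first")
  l2 <- m[cbind(seq_len(nrow(m)), o2)]
  l3 <- (e1 + e2 + e3) - l1 - l2
  list(l1 = l1, l2 = l2, l3 = l3)
}

# principal eigenvector (for the largest-|lambda| eigenvalue) via the spectral
# projector (H - l2 I)(H - l3 I); rows of `H*` are per-voxel components
sym3_principal_vector <- function(h, idx, l1, l2, l3) {
  a11 <- h$h11[idx]; a22 <- h$h22[idx]; a33 <- h$h33[idx]
  a12 <- h$h12[idx]; a13 <- h$h13[idx]; a23 <- h$h23[idx]
  # M = H - l2 I, N = H - l3 I; P = M %*% N, columns span the l1 eigenspace
  m11 <- a11 - l2; m22 <- a22 - l2; m33 <- a33 - l2
  n11 <- a11 - l3; n22 <- a22 - l3; n33 <- a33 - l3
  p11 <- m11 * n11 + a12 * a12 + a13 * a13
  p21 <- a12 * n11 + m22 * a12 + a23 * a13
  p31 <- a13 * n11 + a23 * a12 + m33 * a13
  p12 <- m11 * a12 + a12 * n22 + a13 * a23
  p22 <- a12 * a12 + m22 * n22 + a23 * a23
  p32 <- a13 * a12 + a23 * n22 + m33 * a23
  p13 <- m11 * a13 + a12 * a23 + a13 * n33
  p23 <- a12 * a13 + m22 * a23 + a23 * n33
  p33 <- a13 * a13 + a23 * a23 + m33 * n33
  n1 <- p11^2 + p21^2 + p31^2
  n2 <- p12^2 + p22^2 + p32^2
  n3 <- p13^2 + p23^2 + p33^2
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  v1 <- ifelse(pick == 1, p11, ifelse(pick == 2, p12, p13))
  v2 <- ifelse(pick == 1, p21, ifelse(pick == 2, p22, p23))
  v3 <- ifelse(pick == 1, p31, ifelse(pick == 2, p32, p33))
  nrm <- sqrt(v1^2 + v2^2 + v3^2)
  nrm[nrm < 1e-12] <- 1
  cbind(v1 / nrm, v2 / nrm, v3 / nrm)
}

#' Detect fissure candidate points with a Hessian plate filter
#'
#' Smooths the volume, computes per-voxel Hessian eigenvalues
#' (|λ1| ≥ |λ2| ≥ |λ3|) and the plateness score
#' `S = |λ1| (1 − |λ2|/|λ1|)` for bright plates (λ1 < 0), then suppresses
#' non-maxima along the λ1 eigenvector (the plate normal).
#'
#' @param vol a [volume3d].
#' @param side_mask logical mask of one lung; candidates are restricted to its
#'   interior (two erosions away from the boundary).
#' @param sigma_mm Gaussian smoothing scale.
#' @param threshold absolute plateness threshold; `NULL` uses a quarter of the
#'   maximum score inside the mask.
#' @param smoothed optional pre-smoothed HU array (reused across sides).
#' @return n x 3 matrix of point coordinates in mm (z, y, x), possibly with 0
#'   rows; plateness scores attached as attribute `score`.
#' @export
detect_fissure_points <- function(vol, side_mask, sigma_mm = 1,
                                  threshold = NULL, smoothed = NULL) {
  d <- dim(vol$values)
  if (is.null(smoothed))
    smoothed <- gaussian_smooth(vol$values, vol$spacing, sigma_mm)
  h <- hessian_components(smoothed, vol$spacing)
  interior <- erode_mask(side_mask, 2)
  idx <- which(interior)
  if (length(idx) == 0) return(matrix(numeric(0), 0, 3))
  ev <- sym3_eigenvalues(h$h11[idx], h$h22[idx], h$h33[idx],
                         h$h12[idx], h$h13[idx], h$h23[idx])
  score <- ifelse(ev$l1 < 0 & abs(ev$l1) > 1e-12,
                  abs(ev$l1) * (1 - abs(ev$l2) / pmax(abs(ev$l1), 1e-12)), 0)
  if (is.null(threshold) || is.na(threshold)) threshold <- 0.25 * max(score)
  cand <- which(score > threshold & score > 0)
  if (length(cand) == 0) {
    out <- matrix(numeric(0), 0, 3)
    attr(out, "score") <- numeric(0)
    return(out)
  }
  smap <- array(0, d)
  smap[idx] <- score
  vox <- arrayInd(idx[cand], d)
  e1 <- sym3_principal_vector(h, idx[cand], ev$l1[cand], ev$l2[cand], ev$l3[cand])
  # one-voxel step along the plate normal, in index units
  step <- sweep(e1, 2, vol$spacing, `/`)
  nrm <- pmax(abs(step[, 1]), pmax(abs(step[, 2]), abs(step[, 3])))
  nrm[nrm < 1e-12] <- 1
  step <- step / nrm
  lookup <- function(p) {
    p <- round(p)
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    v <- rep(0, nrow(p))
    v[ok] <- smap[cbind(p[ok, 1], p[ok, 2], p[ok, 3])]
    v
  }
  s_here <- score[cand]
  keep <- s_here >= lookup(vox + step) & s_here >= lookup(vox - step)
  vox <- vox[keep, , drop = FALSE]
  pts <- sweep(sweep(vox - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  attr(pts, "score") <- s_here[keep]
  pts
}

# thin plate spline z = f(y, x); returns an evaluation function
fit_tps2d <- function(y, x, z, reg = 1e-2) {
  n <- length(z)
  r2 <- outer(y, y, `-`)^2 + outer(x, x, `-`)^2
  K <- ifelse(r2 < 1e-12, 0, 0.5 * r2 * log(r2))
  P <- cbind(1, y, x)
  A <- rbind(cbind(K + reg * diag(n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- solve(A, rhs)
  w <- sol[1:n]; a <- sol[n + 1:3]
  function(yq, xq) {
    r2q <- outer(yq, y, `-`)^2 + outer(xq, x, `-`)^2
    Kq <- ifelse(r2q < 1e-12, 0, 0.5 * r2q * log(r2q))
    as.numeric(Kq %*% w) + a[1] + a[2] * yq + a[3] * xq
  }
}

#' Partition one lung into upper and lower lobe groups
#'
#' Fits a regularized thin plate spline surface `z = f(y, x)` through fissure
#' control points and labels voxels above the surface as the upper group and
#' below as the lower group (the right middle lobe counts as lower, so a
#' single surface per lung suffices). With fewer than 6 non-collinear points
#' the fissure is taken as a horizontal plane at a fixed fraction of the
#' cranio-caudal lung extent (a logged fallback).
#'
#' @param points n x 3 matrix of fissure points in mm from
#'   [detect_fissure_points()].
#' @param side_mask logical mask of the lung side.
#' @param vol the originating [volume3d] (geometry).
#' @param fallback_height fraction of the cranio-caudal extent for the
#'   fallback plane.
#' @param reg TPS regularization.
#' @param max_control cap on TPS control points (evenly thinned).
#' @return Integer array over the volume grid: 1 upper, 2 lower inside
#'   `side_mask`, 0 elsewhere. Attribute `fallback` says whether the plane
#'   fallback was used.
#' @export
fit_lobe_surface <- function(points, side_mask, vol, fallback_height = 0.55,
                             reg = 1e-2, max_control = 400) {
  d <- dim(vol$values)
  zc <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  fallback <- FALSE
  surf <- NULL
  if (is.null(points) || nrow(points) < 6 ||
      qr(cbind(1, points[, 2], points[, 3]))$rank < 3) {
    fallback <- TRUE
  } else {
    p <- points
    if (nrow(p) > max_control) {
      o <- order(p[, 2], p[, 3], p[, 1])
      p <- p[o[round(seq(1, nrow(p), length.out = max_control))], , drop = FALSE]
    }
    surf <- tryCatch(fit_tps2d(p[, 2], p[, 3], p[, 1], reg = reg),
                     error = function(e) NULL)
    if (is.null(surf)) fallback <- TRUE
  }
  out <- array(0L, d)
  sel <- which(side_mask)
  if (length(sel) == 0) return(out)
  vox <- arrayInd(sel, d)
  zv <- zc[vox[, 1]]
  if (fallback) {
    message("lobe surface: falling back to a horizontal plane (insufficient fissure points)")
    zr <- range(zv)
    zcut <- zr[1] + fallback_height * (zr[2] - zr[1])
    upper <- zv > zcut
  } else {
    # evaluate the surface once per (y, x) column
    yq <- vol$origin[2] + (vox[, 2] - 1) * vol$spacing[2]
    xq <- vol$origin[3] + (vox[, 3] - 1) * vol$spacing[3]
    col_id <- paste(vox[, 2], vox[, 3])
    first <- !duplicated(col_id)
    fz <- numeric(length(sel))
    zsurf <- rep(NA_real_, sum(first))
    # chunked kernel evaluation to bound memory
    uy <- yq[first]; ux <- xq[first]
    chunk <- 4000
    for (s in seq(1, length(uy), by = chunk)) {
      e <- min(s + chunk - 1, length(uy))
      zsurf[s:e] <- surf(uy[s:e], ux[s:e])
    }
    fz <- zsurf[match(col_id, col_id[first])]
    upper <- zv > fz
  }
  out[sel[upper]] <- 1L
  out[sel[!upper]] <- 2L
  attr(out, "fallback") <- fallback
  out
}
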