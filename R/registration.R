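# Non-rigid alignment of the expiratory lung to the inspiratory lung:
# grid-anchored sparse point sampling from the masks, coherent point drift
# (Gaussian-mixture EM with motion-coherence regularization), and image
# warping through transformed interior landmarks.

#' Sample evenly distributed sparse points from a mask
#'
#' Deterministic, grid-anchored sampling: voxel centers are binned on a
#' physical grid of pitch `target_spacing`; each occupied bin contributes the
#' voxel closest to its bin center. `role = "surface"` restricts to boundary
#' voxels (mask minus its erosion), `role = "interior"` uses all mask voxels.
#'
#' @param mask logical 3-D array.
#' @param geometry a [volume3d] supplying spacing/origin.
#' @param target_spacing grid pitch in mm; must not be below the voxel
#'   spacing.
#' @param role `"surface"` or `"interior"`.
#' @return An object of class `point_set`: list with `coords` (n x 3 mm,
#'   (z, y, x)) and `role`. At least one point is always returned for a
#'   nonempty mask.
#' @export
sample_points <- function(mask, geometry, target_spacing = 10,
                          role = c("interior", "surface")) {
  role <- match.arg(role)
  assert_that(sum(mask) > 0, "mask is empty")
  assert_that(target_spacing >= max(geometry$spacing) - 1e-9,
              "parameter error: target_spacing is below the voxel spacing")
  m <- mask
  if (role == "surface") {
    m <- mask & !erode_mask(mask, 1)
    if (!any(m)) m <- mask
  }
  d <- dim(mask)
  sel <- which(m)
  vox <- arrayInd(sel, d)
  mm <- sweep(sweep(vox - 1, 2, geometry$spacing, `*`), 2, geometry$origin, `+`)
  bin <- floor(sweep(mm, 2, rep(target_spacing, 3), `/`))
  bin_ctr <- (bin + 0.5) * target_spacing
  dist2 <- rowSums((mm - bin_ctr)^2)
  key <- paste(bin[, 1], bin[, 2], bin[, 3])
  o <- order(key, dist2, sel)
  first <- !duplicated(key[o])
  pick <- o[first]
  pick <- pick[order(sel[pick])] # stable, index-ordered output
  structure(list(coords = mm[pick, , drop = FALSE], role = role),
            class = "point_set")
}

point_coords <- function(x) {
  if (inherits(x, "point_set")) x$coords else as.matrix(x)
}

#' Coherent point drift, non-rigid
#'
#' Registers a floating point set onto a reference set with the
#' Gaussian-mixture EM formulation of coherent point drift: the E-step
#' computes soft correspondences under an isotropic mixture centered on the
#' moved floating points with uniform outlier mass `outlier_w`; the M-step
#' solves the regularized kernel system
#' `(G + lambda * sigma2 * diag(1/P1)) W = diag(1/P1) P X − Y` for the
#' Gaussian-kernel weights and updates the mixture variance. Iteration stops
#' at `max_iter` or when the relative change of `sigma2` falls below `tol`.
#'
#' @param floating,reference `point_set`s or n x 3 mm matrices; `floating` is
#'   moved onto `reference`.
#' @param beta Gaussian kernel width (mm) — the coherence scale.
#' @param lambda regularization weight (dimensionless).
#' @param outlier_w uniform outlier mass in \[0, 1).
#' @param max_iter,tol stopping rule.
#' @return An object of class `cpd_result`: kernel weights `W`, the original
#'   floating coordinates, `moved_points`, the per-iteration `sigma2_trace`,
#'   and a `converged` flag. Apply to further points with [cpd_transform()].
#' @export
cpd_nonrigid <- function(floating, reference, beta = 15, lambda = 2,
                         outlier_w = 0.1, max_iter = 150, tol = 1e-5) {
  Y <- point_coords(floating)
  X <- point_coords(reference)
  assert_that(nrow(Y) > 0 && nrow(X) > 0, "point sets must be nonempty")
  assert_that(beta > 0 && lambda > 0, "beta and lambda must be positive")
  assert_that(outlier_w >= 0 && outlier_w < 1, "outlier_w must be in [0, 1)")
  M <- nrow(Y); N <- nrow(X); D <- ncol(Y)
  # normalize both sets to zero mean / unit RMS (standard CPD preprocessing;
  # the mixture's outlier constant is only calibrated in normalized units)
  mu_y <- colMeans(Y); mu_x <- colMeans(X)
  Y0 <- sweep(Y, 2, mu_y)
  X0 <- sweep(X, 2, mu_x)
  s_y <- sqrt(sum(Y0^2) / M); s_x <- sqrt(sum(X0^2) / N)
  s_y <- max(s_y, 1e-9); s_x <- max(s_x, 1e-9)
  Yn <- Y0 / s_y
  Xn <- X0 / s_x
  beta_n <- beta / s_y
  Y_mm <- Y
  Y <- Yn; X <- Xn
  G <- exp(-as.matrix(stats::dist(Y))^2 / (2 * beta_n^2))
  W <- matrix(0, M, D)
  TY <- Y
  dist2 <- function(A, B) {
    # squared distances, rows of A vs rows of B
    outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  }
  sigma2 <- sum(dist2(Y, X)) / (D * M * N)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- dist2(TY, X)
    cst <- (2 * pi * sigma2)^(D / 2) * outlier_w / (1 - outlier_w) * M / N
    Pnum <- exp(-pmax(d2, 0) / (2 * sigma2))
    denom <- colSums(Pnum) + cst
    P <- sweep(Pnum, 2, pmax(denom, .Machine$double.xmin), `/`)
    P1 <- rowSums(P)
    Pt1 <- colSums(P)
    Np <- sum(P1)
    if (Np < .Machine$double.eps) break
    PX <- P %*% X
    dP1inv <- 1 / pmax(P1, 1e-10)
    A <- G + lambda * sigma2 * diag(dP1inv, M)
    rhs <- dP1inv * PX - Y
    W <- tryCatch(solve(A, rhs), error = function(e) {
      A2 <- A + diag(1e-8 * mean(diag(A)), M)
      tryCatch(solve(A2, rhs), error = function(e2)
        stop("numeric error: singular CPD system", call. = FALSE))
    })
    TY <- Y + G %*% W
    s2 <- (sum(Pt1 * rowSums(X^2)) - 2 * sum(PX * TY) +
             sum(P1 * rowSums(TY^2))) / (Np * D)
    s2 <- max(s2, 1e-12)
    trace <- c(trace, s2)
    if (it > 1 && abs(trace[it - 1] - s2) / max(trace[it - 1], 1e-12) < tol) {
      sigma2 <- s2
      converged <- TRUE
      break
    }
    sigma2 <- s2
  }
  moved_mm <- sweep(TY * s_x, 2, mu_x, `+`)
  structure(list(W = W, beta = beta, lambda = lambda, floating = Y_mm,
                 moved_points = moved_mm, sigma2_trace = trace,
                 converged = converged,
                 norm = list(mu_y = mu_y, s_y = s_y, mu_x = mu_x, s_x = s_x,
                             Yn = Yn, beta_n = beta_n)),
            class = "cpd_result")
}

#' Apply a fitted CPD transform to new points
#'
#' @param fit a [cpd_nonrigid()] result.
#' @param pts n x 3 mm matrix (or `point_set`).
#' @return n x 3 matrix of transformed coordinates.
#' @export
cpd_transform <- function(fit, pts) {
  Z <- point_coords(pts)
  nz <- fit$norm
  Zn <- sweep(sweep(Z, 2, nz$mu_y), 2, rep(nz$s_y, 3), `/`)
  Y <- nz$Yn
  d2 <- outer(rowSums(Zn^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(Zn)), rowSums(Y^2)) - 2 * Zn %*% t(Y)
  Gz <- exp(-pmax(d2, 0) / (2 * nz$beta_n^2))
  Tn <- Zn + Gz %*% fit$W
  sweep(Tn * nz$s_x, 2, nz$mu_x, `+`)
}

# 3-D polyharmonic spline interpolant (phi(r) = r) with affine term;
# reproduces affine fields exactly. Returns an evaluation function.
fit_tps3d <- function(anchors, values, reg = 1e-6) {
  n <- nrow(anchors)
  K <- as.matrix(stats::dist(anchors))
  P <- cbind(1, anchors)
  A <- rbind(cbind(K + reg * diag(n), P), cbind(t(P), matrix(0, 4, 4)))
  sol <- solve(A, rbind(values, matrix(0, 4, ncol(values))))
  w <- sol[1:n, , drop = FALSE]
  a <- sol[n + 1:4, , drop = FALSE]
  function(q) {
    out <- matrix(0, nrow(q), ncol(values))
    chunk <- 20000
    for (s in seq(1, nrow(q), by = chunk)) {
      e <- min(s + chunk - 1, nrow(q))
      qq <- q[s:e, , drop = FALSE]
      d2 <- outer(rowSums(qq^2), rep(1, n)) +
        outer(rep(1, nrow(qq)), rowSums(anchors^2)) - 2 * qq %*% t(anchors)
      r <- sqrt(pmax(d2, 0))
      out[s:e, ] <- r %*% w + cbind(1, qq) %*% a
    }
    out
  }
}

#' Warp the expiratory volume onto the inspiratory grid via landmarks
#'
#' Builds a dense displacement field on the output grid by smooth scattered
#' interpolation (3-D polyharmonic spline with affine term) of
#' `landmarks_src − landmarks_dst` anchored at `landmarks_dst`, evaluates it
#' on a coarse lattice, trilinearly upsamples, and resamples the expiratory
#' HU at the displaced positions. Voxels that map outside the expiratory
#' field of view are set to −1024 and flagged invalid.
#'
#' @param expiratory the expiratory [volume3d] (floating image).
#' @param landmarks_src n x 3 mm expiratory-space landmark positions.
#' @param landmarks_dst n x 3 mm positions after CPD (inspiratory space).
#' @param out_geometry [volume3d] defining the output grid (the inspiratory
#'   volume).
#' @param coarse_mm lattice pitch (mm) for dense-field evaluation.
#' @return A [volume3d] (phase expiratory) on the output grid, with a logical
#'   attribute `valid` marking voxels whose source stayed inside the
#'   expiratory field of view.
#' @export
warp_volume <- function(expiratory, landmarks_src, landmarks_dst, out_geometry,
                        coarse_mm = 4) {
  src <- point_coords(landmarks_src)
  dst <- point_coords(landmarks_dst)
  assert_that(nrow(src) == nrow(dst), "landmark sets must have equal length")
  assert_that(nrow(src) >= 4, "need at least 4 landmarks")
  assert_that(qr(cbind(1, dst))$rank == 4,
              "degenerate-geometry error: landmarks are coplanar")
  d <- dim(out_geometry$values)
  # coarse lattice (in continuous voxel index space of the output grid)
  m <- pmax(ceiling((d - 1) * out_geometry$spacing / coarse_mm) + 1, 4)
  ax <- lapply(1:3, function(k) seq(1, d[k], length.out = m[k]))
  cg <- as.matrix(expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]]))
  cg <- cg[order(cg[, 3], cg[, 2], cg[, 1]), , drop = FALSE]
  cg_mm <- sweep(sweep(cg - 1, 2, out_geometry$spacing, `*`), 2,
                 out_geometry$origin, `+`)
  tps <- fit_tps3d(dst, src - dst)
  u_coarse <- tps(cg_mm)
  # upsample each displacement component from the coarse lattice
  full_idx <- do.call(cbind, index_grids(d))
  dim(full_idx) <- c(prod(d), 3)
  map <- sapply(1:3, function(k) (full_idx[, k] - 1) * (m[k] - 1) / (d[k] - 1) + 1)
  u_full <- matrix(0, prod(d), 3)
  for (cmp in 1:3) {
    ca <- array(u_coarse[, cmp], dim = m)
    u_full[, cmp] <- sample_trilinear(ca, map, fill = 0)
  }
  out_mm <- sweep(sweep(full_idx - 1, 2, out_geometry$spacing, `*`), 2,
                  out_geometry$origin, `+`)
  src_mm <- out_mm + u_full
  src_idx <- sweep(sweep(src_mm, 2, expiratory$origin, `-`), 2,
                   expiratory$spacing, `/`) + 1
  hu <- sample_trilinear(expiratory$values, src_idx, fill = NA_real_)
  valid <- !is.na(hu)
  hu[!valid] <- -1024
  vol <- volume3d(array(hu, dim = d), out_geometry$spacing,
                  out_geometry$origin, phase = "expiratory")
  attr(vol, "valid") <- array(valid, dim = d)
  vol
}

#' Register an expiratory scan to the inspiratory scan, per lung
#'
#' Samples surface and interior points from each side's mask in both phases
#' (airway excluded by construction of the side labels), runs CPD per side
#' with the expiratory points floating, moves the expiratory interior points,
#' and warps the expiratory volume onto the inspiratory grid through those
#' landmarks (both sides pooled into one smooth field).
#'
#' @param insp,exp inspiratory and expiratory [volume3d]s.
#' @param regions_insp,regions_exp [region_mask]s for the two phases.
#' @param config a [pipeline_config()] (registration parameters used).
#' @return List: `coreg` (warped expiratory [volume3d] with `valid`
#'   attribute), `cpd` (per-side [cpd_nonrigid()] fits), `landmarks`
#'   (tibble with source, moved positions and displacement).
#' @export
register_pair <- function(insp, exp, regions_insp, regions_exp,
                          config = pipeline_config()) {
  rc <- config$registration
  src_all <- NULL
  dst_all <- NULL
  fits <- list()
  for (s in 1:2) {
    m_i <- regions_insp$side == s
    m_e <- regions_exp$side == s
    if (!any(m_i) || !any(m_e)) next
    ref <- rbind(sample_points(m_i, insp, rc$pitch, "surface")$coords,
                 sample_points(m_i, insp, rc$pitch, "interior")$coords)
    flo_surf <- sample_points(m_e, exp, rc$pitch, "surface")$coords
    flo_int <- sample_points(m_e, exp, rc$pitch, "interior")$coords
    flo <- rbind(flo_surf, flo_int)
    fit <- cpd_nonrigid(flo, ref, beta = rc$beta, lambda = rc$lambda,
                        outlier_w = rc$outlier_w, max_iter = rc$max_iter,
                        tol = rc$tol)
    # landmarks: interior points plus the surface points (the latter pin the
    # displacement field at the lung boundary instead of extrapolating)
    src_all <- rbind(src_all, flo)
    dst_all <- rbind(dst_all, fit$moved_points)
    fits[[c("left", "right")[s]]] <- fit
  }
  assert_that(!is.null(src_all), "no lung side could be registered")
  coreg <- warp_volume(exp, src_all, dst_all, insp, coarse_mm = rc$coarse_mm)
  lm <- tibble::tibble(
    src_z = src_all[, 1], src_y = src_all[, 2], src_x = src_all[, 3],
    dst_z = dst_all[, 1], dst_y = dst_all[, 2], dst_x = dst_all[, 3]
  )
  list(coreg = coreg, cpd = fits, landmarks = lm)
}
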