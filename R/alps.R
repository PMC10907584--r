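#' Fit diffusion tensors by log-linear least squares
#'
#' Per-voxel ordinary least squares on the log signal,
#' `ln S = ln S0 - b g' D g`, solved once for all voxels through a shared
#' design matrix. Noise-free synthetic data round-trip the generating tensor
#' to numerical precision. Non-positive signals are clamped to a small floor
#' before the log (with a message reporting how many), and voxels that are
#' identically zero are skipped.
#'
#' @param dwi_4d 4D array, last dimension indexing volumes.
#' @param bvals numeric b-values per volume (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions (unit norm where b > 0).
#' @param mask optional logical 3D array restricting the fit.
#' @param signal_floor positive floor applied to the signal before `log`.
#' @return a `tensor_field`: list with `components` (4D array `c(grid, 6)`,
#'   ordered Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, in mm^2/s), `s0` (3D array) and
#'   `mask`.
#' @export
fit_tensor <- function(dwi_4d, bvals, bvecs, mask = NULL,
                       signal_floor = 1e-6) {
  dims <- dim(dwi_4d)
  stopifnot(length(dims) == 4L)
  nvol <- dims[4]
  if (length(bvals) != nvol || ncol(bvecs) != nvol)
    stop(sprintf("scheme describes %d volumes but DWI has %d",
                 length(bvals), nvol))
  if (sum(bvals == 0) < 1L) stop("need at least one unweighted (b = 0) volume")
  wt <- bvals > 0
  if (nrow(unique(t(round(bvecs[, wt, drop = FALSE], 8)))) < 6L)
    stop("need at least six unique weighted directions")
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  X <- cbind(1, -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
             -2 * bvals * gx * gy, -2 * bvals * gx * gz,
             -2 * bvals * gy * gz)
  S <- matrix(dwi_4d, nrow = prod(dims[1:3]), ncol = nvol)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  vox <- which(as.vector(mask))
  allzero <- rowSums(abs(S[vox, , drop = FALSE])) == 0
  vox <- vox[!allzero]
  comp <- array(NA_real_, c(dims[1:3], 6))
  s0 <- array(NA_real_, dims[1:3])
  if (length(vox)) {
    Sv <- S[vox, , drop = FALSE]
    nclamp <- sum(Sv <= 0)
    if (nclamp > 0) {
      message(sprintf("fit_tensor: %d non-positive signal values clamped",
                      nclamp))
      Sv[Sv <= 0] <- signal_floor
    }
    beta <- qr.solve(X, t(log(Sv)))       # 7 x nvox
    s0_v <- exp(beta[1, ])
    cm <- matrix(NA_real_, prod(dims[1:3]), 6)
    cm[vox, ] <- t(beta[2:7, , drop = FALSE])
    comp <- array(cm, c(dims[1:3], 6))
    s0v <- rep(NA_real_, prod(dims[1:3])); s0v[vox] <- s0_v
    s0 <- array(s0v, dims[1:3])
  }
  structure(list(components = comp, s0 = s0, mask = mask),
            class = "tensor_field")
}

# 3x3 symmetric tensor from a 6-vector (xx, yy, zz, xy, xz, yz)
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Eigenvalues and fractional anisotropy of fitted tensors
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @param idx integer n x 3 matrix of voxels to evaluate (default: all
#'   fitted voxels).
#' @return data.frame with sorted eigenvalues `ev1 >= ev2 >= ev3` and `fa`.
#' @export
tensor_eigen <- function(field, idx = NULL) {
  if (is.null(idx)) idx <- which(field$mask, arr.ind = TRUE)
  idx <- matrix(as.integer(idx), ncol = 3L)
  out <- matrix(NA_real_, nrow(idx), 4)
  for (r in seq_len(nrow(idx))) {
    v <- field$components[idx[r, 1], idx[r, 2], idx[r, 3], ]
    if (anyNA(v)) next
    ev <- sort(eigen(tensor6_to_mat(v), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    md <- mean(ev)
    fa <- sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
    out[r, ] <- c(ev, fa)
  }
  stats::setNames(as.data.frame(out), c("ev1", "ev2", "ev3", "fa"))
}

#' Spherical region of interest in voxel space
#'
#' Selects voxels whose centers lie within `diameter_mm / 2` of a
#' world-frame center, interpreted through the volume affine. The default
#' centers used for the ALPS index are the right-hemisphere projection-fiber
#' and association-fiber locations at the level of the lateral ventricles,
#' (29, -4, 10) and (41, -4, 10) mm in an MNI-like world frame.
#'
#' @param center_world_mm length-3 world coordinates of the sphere center.
#' @param grid_shape voxel counts of the target grid.
#' @param affine 4x4 grid-to-world matrix.
#' @param diameter_mm sphere diameter (default 4 mm).
#' @return integer n x 3 matrix of 1-based voxel indices.
#' @export
sphere_roi <- function(center_world_mm, grid_shape, affine, diameter_mm = 4) {
  if (!(diameter_mm > 0)) stop("diameter_mm must be > 0")
  vol <- new_volume(array(0, c(2, 2, 2)), affine = affine)
  cc <- world_to_voxel(vol, matrix(center_world_mm, 1))
  if (any(cc < 1 - 1e-9) || any(cc > grid_shape + 1e-9))
    stop("ROI center maps outside the volume grid")
  r <- diameter_mm / 2
  pad <- ceiling(r / vol$voxel_size) + 1
  i0 <- pmax(1, floor(cc - pad)); i1 <- pmin(grid_shape, ceiling(cc + pad))
  idx <- as.matrix(expand.grid(i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]))
  w <- voxel_to_world(vol, idx)
  d2 <- rowSums(sweep(w, 2, as.numeric(center_world_mm))^2)
  keep <- idx[d2 <= r^2 + 1e-12, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("spherical ROI contains no voxel centers (radius below half the voxel size)")
  storage.mode(keep) <- "integer"
  dimnames(keep) <- NULL
  keep
}

roi_mean_components <- function(field, roi_idx) {
  vals <- matrix(NA_real_, nrow(roi_idx), 6)
  for (r in seq_len(nrow(roi_idx)))
    vals[r, ] <- field$components[roi_idx[r, 1], roi_idx[r, 2],
                                  roi_idx[r, 3], ]
  colMeans(vals, na.rm = TRUE)
}

#' DTI-ALPS diffusivity index
#'
#' With x the left-right, y the anterior-posterior and z the
#' inferior-superior world axis, the index is
#' `mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`: diffusivity
#' along the presumed perivascular direction (x, perpendicular to both the
#' projection fibers running along z and the association fibers along y)
#' over the diffusivity across the fibers. Diagonal elements are averaged
#' across each ROI first, then combined ("diagonal" method, the convention
#' of the index's original description). The "eigen" variant instead
#' takes, per ROI, the eigenvalue of the ROI-mean tensor whose eigenvector
#' is nearest the relevant axis — a sensitivity check for the reading in
#' which the second and third eigenvalues compose the index.
#'
#' @param field a `tensor_field`.
#' @param proj_roi,assoc_roi integer n x 3 voxel index matrices from
#'   [sphere_roi()].
#' @param method `"diagonal"` (default) or `"eigen"`.
#' @return list with `index`, `proj` and `assoc` ROI-mean diagonal
#'   diffusivities, and `method`.
#' @export
alps_index <- function(field, proj_roi, assoc_roi,
                       method = c("diagonal", "eigen")) {
  method <- match.arg(method)
  if (nrow(proj_roi) == 0L || nrow(assoc_roi) == 0L)
    stop("both ROIs must be nonempty")
  mp <- roi_mean_components(field, proj_roi)
  ma <- roi_mean_components(field, assoc_roi)
  if (method == "diagonal") {
    num <- mean(c(mp[1], ma[1]))
    den <- mean(c(mp[2], ma[3]))
  } else {
    ax_ev <- function(m6, axis) {
      e <- eigen(tensor6_to_mat(m6), symmetric = TRUE)
      e$values[which.max(abs(e$vectors[axis, ]))]
    }
    num <- mean(c(ax_ev(mp, 1), ax_ev(ma, 1)))
    den <- mean(c(ax_ev(mp, 2), ax_ev(ma, 3)))
  }
  if (!(den > 0)) stop("ALPS denominator is not positive")
  list(index = num / den,
       proj = stats::setNames(mp, c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")),
       assoc = stats::setNames(ma, c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")),
       method = method)
}

#' Compute the ALPS index from DWI inputs
#'
#' Convenience wrapper: fits tensors, places the two default 4-mm spherical
#' ROIs (projection and association fibers) through the volume affine, and
#' returns the index with its per-ROI diagnostics.
#'
#' @param dwi list with `dwi`, `bvals`, `bvecs`, `affine` (as from
#'   [generate_dwi()] or assembled from files).
#' @param proj_center,assoc_center world-frame ROI centers (mm).
#' @param diameter_mm ROI sphere diameter.
#' @param method passed to [alps_index()].
#' @export
compute_alps <- function(dwi, proj_center = c(29, -4, 10),
                         assoc_center = c(41, -4, 10), diameter_mm = 4,
                         method = "diagonal") {
  field <- fit_tensor(dwi$dwi, dwi$bvals, dwi$bvecs)
  grid <- dim(dwi$dwi)[1:3]
  proj <- sphere_roi(proj_center, grid, dwi$affine, diameter_mm)
  assoc <- sphere_roi(assoc_center, grid, dwi$affine, diameter_mm)
  res <- alps_index(field, proj, assoc, method = method)
  res$n_voxels <- c(proj = nrow(proj), assoc = nrow(assoc))
  res
}
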