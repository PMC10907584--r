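#' Shape metrics for one PVS cluster
#'
#' Volume is voxel count times voxel volume. Length and width come from a
#' principal-component decomposition of the voxel-center world coordinates:
#' length is the extent of the projections onto the first principal axis plus
#' one voxel edge (the edge of the grid axis nearest that principal axis),
#' and width the same for the second principal axis. The added edge accounts
#' for the half-voxel of tissue on either side of the outermost centers and
#' makes a single voxel report its sorted edge lengths.
#'
#' @param voxel_indices integer n x 3 matrix of 1-based voxel indices.
#' @param voxel_size_mm voxel edge lengths (mm), used when `affine` is NULL.
#' @param affine optional 4x4 grid-to-world matrix.
#' @return list with `volume_mm3`, `length_mm`, `width_mm`, `centroid_mm`.
#' @export
cluster_metrics <- function(voxel_indices, voxel_size_mm = c(1, 1, 1),
                            affine = NULL) {
  idx <- matrix(as.numeric(voxel_indices), ncol = 3L)
  if (nrow(idx) == 0L) stop("cluster has no voxels")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  vol <- new_volume(array(0, c(2, 2, 2)), affine = affine)  # geometry carrier
  w <- voxel_to_world(vol, idx)
  voxvol <- prod(vol$voxel_size)
  volume_mm3 <- nrow(idx) * voxvol
  centroid <- colMeans(w)
  if (nrow(idx) == 1L) {
    e <- sort(vol$voxel_size, decreasing = TRUE)
    return(list(volume_mm3 = volume_mm3, length_mm = e[1], width_mm = e[2],
                centroid_mm = centroid))
  }
  cv <- stats::cov(w)
  ev <- eigen(cv, symmetric = TRUE)
  axis_extent <- function(v) {
    p <- w %*% v
    nearest <- which.max(abs(v))
    (max(p) - min(p)) + vol$voxel_size[nearest]
  }
  len <- axis_extent(ev$vectors[, 1])
  wid <- axis_extent(ev$vectors[, 2])
  if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
  list(volume_mm3 = volume_mm3, length_mm = len, width_mm = wid,
       centroid_mm = centroid)
}

#' Per-cluster metric table for a label map
#'
#' @param labelmap a `pvs_labelmap` from [cluster_components()] /
#'   [filter_clusters()].
#' @param affine optional grid-to-world matrix for world-frame metrics.
#' @return data.frame with one row per cluster: `cluster_id`, `n_voxels`,
#'   `volume_mm3`, `length_mm`, `width_mm`, `centroid_x/y/z`.
#' @export
labelmap_metrics <- function(labelmap, affine = NULL) {
  stopifnot(inherits(labelmap, "pvs_labelmap"))
  labs <- labelmap$labels
  K <- max(labs)
  out <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                    volume_mm3 = numeric(0), length_mm = numeric(0),
                    width_mm = numeric(0), centroid_x = numeric(0),
                    centroid_y = numeric(0), centroid_z = numeric(0))
  if (K == 0L) return(out)
  idx_all <- which(labs > 0L, arr.ind = TRUE)
  lab_of <- labs[labs > 0L]
  for (k in seq_len(K)) {
    idx <- idx_all[lab_of == k, , drop = FALSE]
    m <- cluster_metrics(idx, labelmap$voxel_size_mm, affine)
    out[k, ] <- list(k, nrow(idx), m$volume_mm3, m$length_mm, m$width_mm,
                     m$centroid_mm[1], m$centroid_mm[2], m$centroid_mm[3])
  }
  out
}

#' Per-subject MV-PVS summary
#'
#' The five per-subject burden metrics: cluster count and total cluster
#' volume, each normalised to the segmented white-matter volume, plus median
#' cluster volume, length and width. A subject with zero clusters gets zero
#' densities and missing medians (never zeros), so downstream models drop
#' rather than bias such records.
#'
#' @param clusters data.frame from [labelmap_metrics()] (needs columns
#'   `volume_mm3`, `length_mm`, `width_mm`).
#' @param wm_volume_mm3 total segmented white-matter volume in mm^3 (> 0).
#' @return one-row data.frame with `pvs_count_per_mm3_wm`,
#'   `pvs_volume_per_mm3_wm`, `median_volume_mm3`, `median_length_mm`,
#'   `median_width_mm`, `n_clusters`.
#' @export
subject_summary <- function(clusters, wm_volume_mm3) {
  if (!(wm_volume_mm3 > 0)) stop("wm_volume_mm3 must be > 0")
  K <- nrow(clusters)
  data.frame(
    pvs_count_per_mm3_wm = K / wm_volume_mm3,
    pvs_volume_per_mm3_wm = sum(clusters$volume_mm3) / wm_volume_mm3,
    median_volume_mm3 = if (K) stats::median(clusters$volume_mm3) else NA_real_,
    median_length_mm = if (K) stats::median(clusters$length_mm) else NA_real_,
    median_width_mm = if (K) stats::median(clusters$width_mm) else NA_real_,
    n_clusters = K)
}

#' White-matter volume of a mask
#'
#' @param wm_mask binary `pvs_volume` or logical array.
#' @param voxel_size_mm used when a bare array is given.
#' @export
wm_volume <- function(wm_mask, voxel_size_mm = c(1, 1, 1)) {
  if (inherits(wm_mask, "pvs_volume")) {
    voxel_size_mm <- wm_mask$voxel_size
    wm_mask <- as_mask_array(wm_mask)
  }
  sum(wm_mask) * prod(voxel_size_mm)
}
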