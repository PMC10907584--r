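#' Detection parameters for MV-PVS segmentation
#'
#' The detector flags white-matter voxels that are locally hypointense:
#' a voxel is a candidate when it sits inside the eroded white-matter mask,
#' its fractional intensity deficit against the neighborhood mean exceeds
#' `diff_threshold` (strictly), and its percentile rank among neighbors falls
#' strictly below `percentile_cut`. Candidates are clustered under
#' corner-to-corner (26) connectivity and clusters must exceed
#' `min_cluster_volume_mm3` strictly.
#'
#' @param diff_threshold fractional deficit versus the neighborhood mean
#'   (default 0.15, i.e. "> 15%", strict).
#' @param percentile_cut neighborhood percentile bound (default 5, the
#'   "bottom fifth percentile", strict).
#' @param neighborhood_radius_mm radius of the spherical neighborhood used
#'   for local statistics; the center voxel is always excluded.
#' @param erosion_voxels iterations of 6-connected white-matter erosion.
#' @param min_cluster_volume_mm3 cluster volume floor in mm^3 (strict ">").
#' @param connectivity 6, 18 or 26 (default 26, corner-to-corner).
#' @param two_sided if `TRUE`, the deficit rule becomes a symmetric
#'   "absolute difference" reading; default is one-sided (hypointense only),
#'   since PVS are CSF-filled and dark on T1.
#' @export
detection_params <- function(diff_threshold = 0.15, percentile_cut = 5,
                             neighborhood_radius_mm = 5,
                             erosion_voxels = 1L,
                             min_cluster_volume_mm3 = 1.0,
                             connectivity = 26L, two_sided = FALSE) {
  if (!(diff_threshold > 0 && diff_threshold < 1))
    stop("diff_threshold must lie in (0, 1)")
  if (!(percentile_cut > 0 && percentile_cut < 100))
    stop("percentile_cut must lie in (0, 100)")
  if (!(min_cluster_volume_mm3 > 0)) stop("min_cluster_volume_mm3 must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(diff_threshold = diff_threshold,
                 percentile_cut = percentile_cut,
                 neighborhood_radius_mm = neighborhood_radius_mm,
                 erosion_voxels = as.integer(erosion_voxels),
                 min_cluster_volume_mm3 = min_cluster_volume_mm3,
                 connectivity = as.integer(connectivity),
                 two_sided = two_sided),
            class = "detection_params")
}

# add src values of `arr` shifted by offset (dx,dy,dz) into dest positions;
# returns list(src=, dst=) index lists for the in-grid overlap
shift_slices <- function(dims, off) {
  lo_s <- pmax(1L, 1L + off); hi_s <- pmin(dims, dims + off)
  if (any(lo_s > hi_s)) return(NULL)
  list(src = list(lo_s[1]:hi_s[1], lo_s[2]:hi_s[2], lo_s[3]:hi_s[3]),
       dst = list((lo_s[1] - off[1]):(hi_s[1] - off[1]),
                  (lo_s[2] - off[2]):(hi_s[2] - off[2]),
                  (lo_s[3] - off[3]):(hi_s[3] - off[3])))
}

#' Erode a binary mask
#'
#' Morphological erosion with the 6-connected (face-neighbor) structuring
#' element; voxels outside the grid count as background.
#'
#' @param mask binary `pvs_volume` or logical array.
#' @param iterations number of erosion passes (>= 0).
#' @return object of the same kind as the input (volume in, volume out).
#' @export
erode_mask <- function(mask, iterations = 1L) {
  is_vol <- inherits(mask, "pvs_volume")
  m <- as_mask_array(mask)
  if (iterations < 0) stop("iterations must be >= 0")
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  dims <- dim(m)
  for (it in seq_len(iterations)) {
    keep <- m
    for (r in seq_len(nrow(offs))) {
      nb <- array(FALSE, dims)  # out-of-grid neighbor = background
      sl <- shift_slices(dims, offs[r, ])
      nb[sl$dst[[1]], sl$dst[[2]], sl$dst[[3]]] <-
        m[sl$src[[1]], sl$src[[2]], sl$src[[3]]]
      keep <- keep & nb
    }
    m <- keep
  }
  if (is_vol) new_volume(m, affine = mask$affine) else m
}

#' Local neighborhood mean and percentile rank
#'
#' For every voxel, computes the mean intensity of brain-mask voxels whose
#' centers lie within `radius_mm` of the voxel's center (excluding the voxel
#' itself), and the voxel's percentile rank among those neighbors: the
#' fraction of neighbors strictly below its intensity, times 100. Equal
#' intensities do not count as below. Voxels with no in-mask neighbor get
#' `NA` in both maps.
#'
#' @param volume a `pvs_volume` (typically a T1-weighted image).
#' @param brain_mask binary volume restricting which voxels may serve as
#'   neighbors.
#' @param radius_mm spherical neighborhood radius; must be at least the
#'   largest voxel edge so every interior voxel has neighbors.
#' @return list with `mean_map` and `rank_map` (3D arrays).
#' @export
local_statistics <- function(volume, brain_mask, radius_mm) {
  m <- as_mask_array(brain_mask)
  vals <- volume$data
  dims <- dim(vals)
  if (radius_mm < max(volume$voxel_size))
    stop("radius_mm must be at least the largest voxel edge length")
  offs <- sphere_offsets(volume$voxel_size, radius_mm)
  sum_map <- array(0, dims)
  cnt_map <- array(0L, dims)
  below <- array(0L, dims)
  mnum <- array(as.double(m), dims)
  vm <- vals * mnum  # zero outside mask so masked sums are a plain add
  for (r in seq_len(nrow(offs))) {
    sl <- shift_slices(dims, offs[r, ])
    if (is.null(sl)) next
    d1 <- sl$dst[[1]]; d2 <- sl$dst[[2]]; d3 <- sl$dst[[3]]
    s1 <- sl$src[[1]]; s2 <- sl$src[[2]]; s3 <- sl$src[[3]]
    sum_map[d1, d2, d3] <- sum_map[d1, d2, d3] + vm[s1, s2, s3]
    cnt_map[d1, d2, d3] <- cnt_map[d1, d2, d3] + mnum[s1, s2, s3]
    below[d1, d2, d3] <- below[d1, d2, d3] +
      mnum[s1, s2, s3] * (vals[s1, s2, s3] < vals[d1, d2, d3])
  }
  mean_map <- sum_map / cnt_map
  mean_map[cnt_map == 0] <- NA_real_
  rank_map <- 100 * below / cnt_map
  rank_map[cnt_map == 0] <- NA_real_
  list(mean_map = mean_map, rank_map = rank_map)
}

#' Flag candidate PVS voxels
#'
#' Applies the three detection rules: membership in the eroded white-matter
#' mask, fractional intensity deficit strictly above `diff_threshold`, and
#' neighborhood percentile rank strictly below `percentile_cut`. Voxels whose
#' neighborhood mean is not positive cannot be assessed and are skipped with
#' a warning.
#'
#' @param volume `pvs_volume` intensity image.
#' @param eroded_wm binary volume, the eroded white-matter mask.
#' @param params [detection_params()].
#' @param stats optional precomputed [local_statistics()] output (the brain
#'   mask used for the statistics may be wider than the eroded mask).
#' @return logical 3D array of candidate voxels.
#' @export
candidate_voxels <- function(volume, eroded_wm, params = detection_params(),
                             stats = NULL) {
  if (is.null(stats))
    stats <- local_statistics(volume, eroded_wm,
                              params$neighborhood_radius_mm)
  ew <- as_mask_array(eroded_wm)
  mu <- stats$mean_map
  bad <- ew & !is.na(mu) & mu <= 0
  if (any(bad))
    warning(sprintf("%d voxels skipped: non-positive neighborhood mean",
                    sum(bad)))
  deficit <- (mu - volume$data) / mu
  if (params$two_sided) deficit <- abs(deficit)
  cand <- ew & !is.na(mu) & mu > 0 &
    deficit > params$diff_threshold &
    !is.na(stats$rank_map) & stats$rank_map < params$percentile_cut
  cand & !bad
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                 "26" = ord >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Cluster candidate voxels into connected components
#'
#' Components are found under the requested connectivity (26 by default,
#' i.e. face, edge and corner neighbors all connect). Labels are assigned in
#' decreasing component size; ties broken by the smallest linear
#' (column-major scan) index of a member voxel.
#'
#' @param candidates logical 3D array (or binary `pvs_volume`).
#' @param connectivity 6, 18 or 26.
#' @param voxel_size_mm voxel edge lengths carried into the label map.
#' @return a `pvs_labelmap`: list with `labels` (integer array, 0 background)
#'   and `voxel_size_mm`.
#' @export
cluster_components <- function(candidates, connectivity = 26L,
                               voxel_size_mm = c(1, 1, 1)) {
  if (inherits(candidates, "pvs_volume")) {
    voxel_size_mm <- candidates$voxel_size
    candidates <- as_mask_array(candidates)
  }
  dims <- dim(candidates)
  offs <- connectivity_offsets(connectivity)
  lin <- which(candidates)                    # column-major order
  labels <- array(0L, dims)
  if (length(lin) == 0L)
    return(structure(list(labels = labels, voxel_size_mm = voxel_size_mm),
                     class = "pvs_labelmap"))
  in_set <- logical(prod(dims)); in_set[lin] <- TRUE
  seen <- logical(prod(dims))
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  members <- list()
  k <- 0L
  for (start in lin) {
    if (seen[start]) next
    k <- k + 1L
    stack <- start
    seen[start] <- TRUE
    got <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      got <- c(got, v)
      v0 <- v - 1L
      i <- v0 %% nx; rest <- v0 %/% nx
      j <- rest %% dims[2]; kk <- rest %/% dims[2]
      ni <- i + offs[, 1]; nj <- j + offs[, 2]; nk <- kk + offs[, 3]
      ok <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] &
        nk >= 0 & nk < dims[3]
      nb <- 1L + ni[ok] + nx * nj[ok] + nxy * nk[ok]
      nb <- nb[in_set[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    members[[k]] <- sort(got)
  }
  sizes <- lengths(members)
  firsts <- vapply(members, `[`, integer(1), 1L)
  ord <- order(-sizes, firsts)
  for (new_lab in seq_along(ord)) labels[members[[ord[new_lab]]]] <- new_lab
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm),
            class = "pvs_labelmap")
}

#' Remove clusters at or below a volume floor
#'
#' Keeps clusters whose volume (voxel count times voxel volume) strictly
#' exceeds `min_volume_mm3`, relabelling the survivors 1..K' while
#' preserving the size ordering.
#'
#' @param labelmap a `pvs_labelmap` from [cluster_components()].
#' @param min_volume_mm3 strict volume floor (default 1 mm^3).
#' @export
filter_clusters <- function(labelmap, min_volume_mm3 = 1.0) {
  stopifnot(inherits(labelmap, "pvs_labelmap"))
  labs <- labelmap$labels
  K <- max(labs)
  if (K == 0L) return(labelmap)
  voxvol <- prod(labelmap$voxel_size_mm)
  counts <- tabulate(labs[labs > 0L], nbins = K)
  keep <- which(counts * voxvol > min_volume_mm3)
  remap <- integer(K)
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(labs))
  nz <- labs > 0L
  out[nz] <- remap[labs[nz]]
  structure(list(labels = out, voxel_size_mm = labelmap$voxel_size_mm),
            class = "pvs_labelmap")
}

#' Run the full MV-PVS detector
#'
#' Erodes the white-matter mask, computes local statistics, applies the
#' heterogeneity rules, clusters the candidates and filters small clusters.
#'
#' @param t1 `pvs_volume` T1-weighted image.
#' @param wm_mask binary `pvs_volume` white-matter mask on the same grid.
#' @param params [detection_params()].
#' @return list with `labelmap` (filtered `pvs_labelmap`), `candidates`
#'   (logical array), `eroded_wm` (logical array) and `params`.
#' @export
detect_pvs <- function(t1, wm_mask, params = detection_params()) {
  check_same_grid(t1, wm_mask, c("T1", "WM mask"))
  wm <- as_mask_array(wm_mask)
  ew <- erode_mask(wm, params$erosion_voxels)
  # neighborhood statistics draw on the full WM mask; the eroded mask only
  # restricts which voxels may become candidates
  stats <- local_statistics(t1, wm, params$neighborhood_radius_mm)
  cand <- candidate_voxels(t1, ew, params, stats = stats)
  lm0 <- cluster_components(cand, params$connectivity, t1$voxel_size)
  labelmap <- filter_clusters(lm0, params$min_cluster_volume_mm3)
  list(labelmap = labelmap, candidates = cand, eroded_wm = ew,
       params = params)
}
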