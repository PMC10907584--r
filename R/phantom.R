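#' Specify a tubular pseudo-PVS for a phantom
#'
#' MV-PVS appear as thin hypointense tubules within white matter on
#' T1-weighted images; the phantom emulates them as finite cylinders with a
#' fractional intensity deficit relative to the surrounding white matter.
#'
#' @param endpoint_a_mm,endpoint_b_mm world coordinates (mm) of the tube
#'   axis endpoints.
#' @param radius_mm tube radius in mm (> 0).
#' @param contrast_fraction fractional intensity drop relative to local white
#'   matter, in (0, 1); tube voxels get `wm_intensity * (1 - contrast_fraction)`.
#' @export
tube_spec <- function(endpoint_a_mm, endpoint_b_mm, radius_mm,
                      contrast_fraction) {
  stopifnot(length(endpoint_a_mm) == 3L, length(endpoint_b_mm) == 3L)
  if (!(radius_mm > 0)) stop("radius_mm must be > 0")
  if (!(contrast_fraction > 0 && contrast_fraction < 1))
    stop("contrast_fraction must lie strictly in (0, 1)")
  if (all(endpoint_a_mm == endpoint_b_mm))
    stop("tube endpoints must be distinct")
  structure(list(endpoint_a_mm = as.numeric(endpoint_a_mm),
                 endpoint_b_mm = as.numeric(endpoint_b_mm),
                 radius_mm = radius_mm,
                 contrast_fraction = contrast_fraction),
            class = "tube_spec")
}

#' Specify a T1-like white-matter phantom
#'
#' @param grid_shape integer length-3 voxel counts (all >= 8).
#' @param voxel_size_mm numeric length-3 voxel edge lengths (mm, > 0).
#'   Typical acquisition geometries are 0.94 mm isotropic and
#'   0.5 x 0.5 x 1.0 mm.
#' @param wm_intensity baseline white-matter intensity (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (same units, >= 0).
#' @param tubes list of [tube_spec()] objects embedded in the white matter.
#' @param wm_margin_voxels voxels trimmed from each face to form the
#'   white-matter mask box.
#' @param seed integer RNG seed; equal seeds give bit-identical phantoms.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = c(1, 1, 1),
                         wm_intensity = 100,
                         noise_sd = 0,
                         tubes = list(),
                         wm_margin_voxels = 2L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (!(length(grid_shape) == 3L && all(grid_shape >= 8L)))
    stop("grid_shape must be three counts, all >= 8")
  if (!(length(voxel_size_mm) == 3L && all(voxel_size_mm > 0)))
    stop("voxel_size_mm must be three positive edge lengths")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(vapply(tubes, inherits, logical(1), "tube_spec")))
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 wm_intensity = wm_intensity, noise_sd = noise_sd,
                 tubes = tubes, wm_margin_voxels = as.integer(wm_margin_voxels),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# 1-based voxel indices whose centers lie inside the finite cylinder
# (axial projection within [0, L], radial distance <= r; no end caps)
tube_voxels <- function(tube, vol) {
  a <- tube$endpoint_a_mm
  b <- tube$endpoint_b_mm
  axis <- b - a
  len <- sqrt(sum(axis^2))
  u <- axis / len
  # bounding box in voxel space, padded by the radius
  lo <- pmin(a, b) - tube$radius_mm
  hi <- pmax(a, b) + tube$radius_mm
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  vc <- world_to_voxel(vol, corners)
  i0 <- pmax(1L, floor(apply(vc, 2, min)))
  i1 <- pmin(dim(vol$data), ceiling(apply(vc, 2, max)))
  if (any(i0 > i1)) return(matrix(integer(0), 0, 3))
  idx <- as.matrix(expand.grid(i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]))
  w <- voxel_to_world(vol, idx)
  rel <- sweep(w, 2, a)
  t_ax <- rel %*% u
  d2 <- rowSums(rel^2) - t_ax^2
  keep <- t_ax >= 0 & t_ax <= len & d2 <= tube$radius_mm^2 + 1e-12
  m <- idx[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j", "k")
  m
}

#' Generate a T1-like phantom with embedded tubular PVS
#'
#' Builds a white-matter box at `wm_intensity`, carves each tube down to
#' `wm_intensity * (1 - contrast_fraction)` at voxels whose centers fall
#' inside the cylinder, then adds Gaussian noise within the mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with `t1` (a [new_volume()]), `wm_mask` (logical volume) and
#'   `truth`, a list (one entry per tube) of n x 3 ground-truth voxel index
#'   matrices.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  vol <- new_volume(array(0, dim = dims), voxel_size = spec$voxel_size_mm)
  m <- spec$wm_margin_voxels
  mask <- array(FALSE, dim = dims)
  mask[(1 + m):(dims[1] - m), (1 + m):(dims[2] - m), (1 + m):(dims[3] - m)] <- TRUE
  arr <- array(0, dim = dims)
  arr[mask] <- spec$wm_intensity

  # world-space bounds of the voxel-center lattice
  lo_w <- voxel_to_world(vol, matrix(c(1, 1, 1), 1))
  hi_w <- voxel_to_world(vol, matrix(dims, 1))
  truth <- vector("list", length(spec$tubes))
  for (t in seq_along(spec$tubes)) {
    tube <- spec$tubes[[t]]
    for (p in list(tube$endpoint_a_mm, tube$endpoint_b_mm)) {
      if (any(p - tube$radius_mm < pmin(lo_w, hi_w)) ||
          any(p + tube$radius_mm > pmax(lo_w, hi_w)))
        stop(sprintf("tube %d extends outside the phantom grid", t))
    }
    vox <- tube_voxels(tube, vol)
    arr[vox] <- spec$wm_intensity * (1 - tube$contrast_fraction)
    truth[[t]] <- vox
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    arr[mask] <- arr[mask] + stats::rnorm(sum(mask), 0, spec$noise_sd)
  }
  list(t1 = new_volume(arr, affine = vol$affine),
       wm_mask = new_volume(mask, affine = vol$affine),
       truth = truth)
}
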