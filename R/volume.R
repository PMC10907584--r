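#' 3D volume with voxel geometry
#'
#' A `pvs_volume` bundles a 3D numeric array with its grid-to-world affine
#' (RAS+ convention). Voxel edge lengths are derived from the affine column
#' norms, so a volume carries one authoritative geometry.
#'
#' @param data 3D numeric or logical array.
#' @param voxel_size numeric length-3 voxel edge lengths in mm, used to build
#'   a diagonal affine when `affine` is not given.
#' @param affine 4x4 grid-to-world matrix mapping 0-based voxel indices to
#'   world mm coordinates. Defaults to `diag(c(voxel_size, 1))`.
#' @return An object of class `pvs_volume` with elements `data`, `affine`
#'   and `voxel_size`.
#' @export
new_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop("`data` must be a 3D array")
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(data = data, affine = affine, voxel_size = vs),
            class = "pvs_volume")
}

#' @export
print.pvs_volume <- function(x, ...) {
  cat(sprintf("<pvs_volume> %s voxels, %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.pvs_volume <- function(x) dim(x$data)

#' Map 1-based voxel indices to world coordinates
#'
#' @param vol a `pvs_volume`.
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of world mm coordinates of the voxel centers.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx - 1, 2, 0) %*% t(vol$affine[1:3, 1:3]) +
    matrix(vol$affine[1:3, 4], nrow(idx), 3, byrow = TRUE)
}

#' Map world coordinates to continuous 1-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param world n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @export
world_to_voxel <- function(vol, world) {
  world <- matrix(as.numeric(world), ncol = 3L)
  inv <- solve(vol$affine)
  world %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(world), 3, byrow = TRUE) + 1
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [new_volume()] object; the stored xform becomes the affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  new_volume(arr, affine = aff)
}

#' Write a NIfTI-1 volume
#'
#' Data are stored as float64 so round trips are bit-exact.
#'
#' @param vol a `pvs_volume` (logical data are written as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  arr <- vol$data
  if (is.logical(arr)) arr <- array(as.double(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check two volumes share a grid
#'
#' @param a,b `pvs_volume` objects, e.g. a T1 volume and its mask.
#' @param what names used in the error message.
#' @export
check_same_grid <- function(a, b, what = c("volume", "mask")) {
  if (!all(dim(a$data) == dim(b$data)))
    stop(sprintf("grid mismatch: %s is %s but %s is %s", what[1],
                 paste(dim(a$data), collapse = "x"), what[2],
                 paste(dim(b$data), collapse = "x")))
  invisible(TRUE)
}

# logical mask with sanity check; accepts 0/1 numeric
as_mask_array <- function(mask) {
  m <- if (inherits(mask, "pvs_volume")) mask$data else mask
  if (is.logical(m)) return(m)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1))) stop("mask must be binary (0/1 or logical)")
  array(m != 0, dim = dim(m))
}

# integer offsets (n x 3) whose world displacement has norm <= radius_mm,
# excluding the zero offset
sphere_offsets <- function(voxel_size, radius_mm) {
  k <- floor(radius_mm / voxel_size)
  g <- as.matrix(expand.grid(dx = -k[1]:k[1], dy = -k[2]:k[2], dz = -k[3]:k[3]))
  d2 <- (g[, 1] * voxel_size[1])^2 + (g[, 2] * voxel_size[2])^2 +
    (g[, 3] * voxel_size[3])^2
  g <- g[d2 <= radius_mm^2 & d2 > 0, , drop = FALSE]
  if (nrow(g) == 0)
    stop("radius_mm too small: no neighboring voxel centers within radius")
  g
}
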