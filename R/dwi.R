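#' Default diffusion-encoding scheme
#'
#' Two unweighted (b = 0) volumes followed by 60 directions at
#' b = 1000 s/mm^2, mirroring the acquisition used for the bed-rest DWI.
#' Directions are a deterministic Fibonacci-hemisphere spread (approximately
#' uniform over the half-sphere, which is sufficient for single-shell DTI).
#'
#' @param n_directions number of weighted directions.
#' @param b b-value (s/mm^2) for the weighted volumes.
#' @param n_b0 number of leading unweighted volumes.
#' @return list with `bvals` (length n_b0 + n_directions) and `bvecs`
#'   (3 x n matrix, unit columns for weighted volumes, zero for b = 0).
#' @export
default_scheme <- function(n_directions = 60L, b = 1000, n_b0 = 2L) {
  i <- seq_len(n_directions)
  z <- (i - 0.5) / n_directions          # hemisphere, z in (0, 1)
  phi <- (i - 1) * pi * (3 - sqrt(5))    # golden angle
  r <- sqrt(1 - z^2)
  g <- rbind(r * cos(phi), r * sin(phi), z)
  bvecs <- cbind(matrix(0, 3, n_b0), g)
  bvals <- c(rep(0, n_b0), rep(b, n_directions))
  list(bvals = bvals, bvecs = bvecs)
}

#' Specify a synthetic DWI acquisition
#'
#' @param tensor_field either a single 3x3 symmetric positive-definite tensor
#'   (mm^2/s), applied everywhere, or a 4D array `c(grid, 6)` of per-voxel
#'   components ordered (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @param grid_shape voxel counts (ignored when `tensor_field` is 4D).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param scheme list with `bvals`/`bvecs` as from [default_scheme()].
#' @param s0 unweighted signal amplitude.
#' @param noise_sd noise SD; `noise_model` chooses additive Gaussian
#'   (default) or Rician noise.
#' @param affine optional 4x4 grid-to-world matrix.
#' @param seed integer RNG seed.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @export
dwi_spec <- function(tensor_field, grid_shape = c(16, 16, 16),
                     voxel_size_mm = c(1.8, 1.8, 2.7),
                     scheme = default_scheme(), s0 = 1000,
                     noise_sd = 0, affine = NULL, seed = 1L,
                     noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  if (length(scheme$bvals) != ncol(scheme$bvecs))
    stop("bvals and bvecs describe different numbers of volumes")
  wt <- scheme$bvals > 0
  nrm <- sqrt(colSums(scheme$bvecs[, wt, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("weighted gradient directions must have unit norm")
  if (is.matrix(tensor_field)) {
    check_spd(tensor_field)
    tf <- array(0, dim = c(grid_shape, 6))
    comp <- tensor_field[c(1, 5, 9, 2, 3, 6)]  # xx yy zz xy xz yz
    for (c6 in 1:6) tf[, , , c6] <- comp[c6]
  } else {
    stopifnot(length(dim(tensor_field)) == 4L, dim(tensor_field)[4] == 6L)
    tf <- tensor_field
    grid_shape <- dim(tf)[1:3]
    check_spd_field(tf)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(tensor_field = tf, grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm, scheme = scheme, s0 = s0,
                 noise_sd = noise_sd, affine = affine, seed = as.integer(seed),
                 noise_model = noise_model),
            class = "dwi_spec")
}

check_spd <- function(D) {
  if (!isTRUE(all.equal(D, t(D)))) stop("tensor must be symmetric")
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("tensor must be symmetric positive-definite")
  invisible(TRUE)
}

# vectorised SPD check via leading principal minors
check_spd_field <- function(tf) {
  xx <- tf[, , , 1]; yy <- tf[, , , 2]; zz <- tf[, , , 3]
  xy <- tf[, , , 4]; xz <- tf[, , , 5]; yz <- tf[, , , 6]
  m1 <- xx
  m2 <- xx * yy - xy^2
  m3 <- xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) +
    xz * (xy * yz - yy * xz)
  if (any(m1 <= 0 | m2 <= 0 | m3 <= 0))
    stop("tensor field contains a non-positive-definite tensor")
  invisible(TRUE)
}

#' Generate diffusion-weighted volumes from a tensor field
#'
#' Noise-free signal follows the single-tensor model
#' `S = s0 * exp(-b * g' D g)` per voxel and direction.
#'
#' @param spec a [dwi_spec()].
#' @return list with `dwi` (4D array), `bvals`, `bvecs` (3 x n), and
#'   `affine`.
#' @export
generate_dwi <- function(spec) {
  stopifnot(inherits(spec, "dwi_spec"))
  tf <- spec$tensor_field
  dims <- spec$grid_shape
  nvol <- length(spec$scheme$bvals)
  out <- array(0, dim = c(dims, nvol))
  for (v in seq_len(nvol)) {
    b <- spec$scheme$bvals[v]
    g <- spec$scheme$bvecs[, v]
    q <- tf[, , , 1] * g[1]^2 + tf[, , , 2] * g[2]^2 + tf[, , , 3] * g[3]^2 +
      2 * (tf[, , , 4] * g[1] * g[2] + tf[, , , 5] * g[1] * g[3] +
             tf[, , , 6] * g[2] * g[3])
    out[, , , v] <- spec$s0 * exp(-b * q)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    if (spec$noise_model == "gaussian") {
      out <- out + array(stats::rnorm(length(out), 0, spec$noise_sd), dim(out))
    } else {
      n1 <- array(stats::rnorm(length(out), 0, spec$noise_sd), dim(out))
      n2 <- array(stats::rnorm(length(out), 0, spec$noise_sd), dim(out))
      out <- sqrt((out + n1)^2 + n2^2)
    }
  }
  affine <- if (is.null(spec$affine)) diag(c(spec$voxel_size_mm, 1)) else spec$affine
  list(dwi = out, bvals = spec$scheme$bvals, bvecs = spec$scheme$bvecs,
       affine = affine)
}

#' Read / write FSL-dialect bval and bvec files
#'
#' `bval` is a single whitespace-separated row; `bvec` has one row per axis.
#'
#' @param path file path.
#' @name fsl_gradients
#' @export
read_bvals <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}

#' @rdname fsl_gradients
#' @export
read_bvecs <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (nrow(m) != 3L) stop("bvec file must have exactly three rows (x, y, z)")
  dimnames(m) <- NULL
  m
}

#' @rdname fsl_gradients
#' @param bvals numeric vector of b-values.
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname fsl_gradients
#' @param bvecs 3 x n matrix of gradient directions.
#' @export
write_bvecs <- function(bvecs, path) {
  stopifnot(nrow(bvecs) == 3L)
  writeLines(apply(bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), path)
  invisible(path)
}

#' Write a 4D DWI dataset to NIfTI plus FSL gradient files
#'
#' @param dwi list as returned by [generate_dwi()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, prefix) {
  img <- RNifti::asNifti(dwi$dwi, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(dwi$affine, code = 2L))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  write_bvals(dwi$bvals, paste0(prefix, ".bval"))
  write_bvecs(dwi$bvecs, paste0(prefix, ".bvec"))
  invisible(prefix)
}
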