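# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain
# per-voxel loops and a queue-based flood fill.

naive_erode <- function(mask, iterations = 1L) {
  dims <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- array(FALSE, dims)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        if (!mask[i, j, k]) next
        ok <- TRUE
        for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
          p <- c(i, j, k) + d
          if (any(p < 1) || any(p > dims) || !mask[p[1], p[2], p[3]]) {
            ok <- FALSE; break
          }
        }
        out[i, j, k] <- ok
      }
    mask <- out
  }
  mask
}

# per-voxel neighborhood mean / strict-below percentile rank
naive_local_stats <- function(vals, mask, voxel_size, radius_mm) {
  dims <- dim(vals)
  mean_map <- array(NA_real_, dims)
  rank_map <- array(NA_real_, dims)
  k <- floor(radius_mm / voxel_size)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (kk in seq_len(dims[3])) {
      nb <- c()
      for (di in -k[1]:k[1]) for (dj in -k[2]:k[2]) for (dk in -k[3]:k[3]) {
        if (di == 0 && dj == 0 && dk == 0) next
        d2 <- (di * voxel_size[1])^2 + (dj * voxel_size[2])^2 +
          (dk * voxel_size[3])^2
        if (d2 > radius_mm^2) next
        p <- c(i + di, j + dj, kk + dk)
        if (any(p < 1) || any(p > dims)) next
        if (!mask[p[1], p[2], p[3]]) next
        nb <- c(nb, vals[p[1], p[2], p[3]])
      }
      if (length(nb)) {
        mean_map[i, j, kk] <- mean(nb)
        rank_map[i, j, kk] <- 100 * sum(nb < vals[i, j, kk]) / length(nb)
      }
    }
  list(mean_map = mean_map, rank_map = rank_map)
}

# queue flood fill over a logical array
naive_components <- function(cand, connectivity = 26L) {
  dims <- dim(cand)
  lab <- array(0L, dims)
  comps <- list()
  nb_ok <- function(d) {
    s <- sum(abs(d))
    (connectivity == 26L && s >= 1) ||
      (connectivity == 18L && s >= 1 && s <= 2) ||
      (connectivity == 6L && s == 1)
  }
  deltas <- list()
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    d <- c(di, dj, dk)
    if (!all(d == 0) && nb_ok(d)) deltas[[length(deltas) + 1L]] <- d
  }
  visited <- array(FALSE, dims)
  for (v in which(cand)) {
    if (visited[v]) next
    queue <- list(arrayInd(v, dims)[1, ])
    visited[v] <- TRUE
    got <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      got <- c(got, (p[3] - 1) * dims[1] * dims[2] + (p[2] - 1) * dims[1] + p[1])
      for (d in deltas) {
        q <- p + d
        if (any(q < 1) || any(q > dims)) next
        ql <- (q[3] - 1) * dims[1] * dims[2] + (q[2] - 1) * dims[1] + q[1]
        if (cand[ql] && !visited[ql]) {
          visited[ql] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(got)
  }
  # label by decreasing size, ties by smallest member linear index
  if (length(comps)) {
    ord <- order(-lengths(comps), vapply(comps, min, numeric(1)))
    for (newl in seq_along(ord)) lab[comps[[ord[newl]]]] <- newl
  }
  lab
}

# complete rule-by-rule detector: eroded-mask membership, strict deficit,
# strict percentile, flood fill, strict volume filter
naive_detect <- function(vals, wm, voxel_size, radius_mm,
                         diff_threshold = 0.15, percentile_cut = 5,
                         erosion = 1L, min_volume = 1.0,
                         connectivity = 26L) {
  ew <- naive_erode(wm, erosion)
  st <- naive_local_stats(vals, wm, voxel_size, radius_mm)
  dims <- dim(vals)
  cand <- array(FALSE, dims)
  for (v in seq_len(prod(dims))) {
    if (!ew[v] || is.na(st$mean_map[v]) || st$mean_map[v] <= 0) next
    deficit <- (st$mean_map[v] - vals[v]) / st$mean_map[v]
    cand[v] <- deficit > diff_threshold && st$rank_map[v] < percentile_cut
  }
  lab <- naive_components(cand, connectivity)
  K <- max(lab)
  if (K > 0) {
    voxvol <- prod(voxel_size)
    counts <- tabulate(lab[lab > 0], nbins = K)
    keep <- which(counts * voxvol > min_volume)
    out <- array(0L, dims)
    for (newl in seq_along(keep)) out[lab == keep[newl]] <- newl
    lab <- out
  }
  list(candidates = cand, labels = lab)
}

# brute-force PCA metrics for a voxel cluster (world frame)
naive_cluster_metrics <- function(idx, voxel_size) {
  w <- sweep(matrix(as.numeric(idx), ncol = 3) - 1, 2, voxel_size, `*`)
  n <- nrow(w)
  vol <- n * prod(voxel_size)
  if (n == 1) {
    e <- sort(voxel_size, decreasing = TRUE)
    return(list(volume_mm3 = vol, length_mm = e[1], width_mm = e[2]))
  }
  cc <- sweep(w, 2, colMeans(w))
  sv <- svd(cc)
  ext <- function(v) {
    p <- w %*% v
    diff(range(p)) + voxel_size[which.max(abs(v))]
  }
  vals <- sort(c(ext(sv$v[, 1]), ext(sv$v[, 2])), decreasing = TRUE)
  list(volume_mm3 = vol, length_mm = vals[1], width_mm = vals[2])
}

# random test volume: noisy white-matter box with a few dark blobs
random_volume <- function(dims, seed, voxel_size = c(1, 1, 1),
                          n_blobs = 3) {
  set.seed(seed)
  vals <- array(stats::rnorm(prod(dims), 100, 10), dims)
  wm <- array(FALSE, dims)
  wm[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- TRUE
  for (b in seq_len(n_blobs)) {
    c0 <- sapply(dims, function(n) sample(4:(n - 3), 1))
    span <- sample(1:2, 3, replace = TRUE)
    vals[(c0[1]):(c0[1] + span[1]), (c0[2]):(c0[2] + span[2]),
         (c0[3]):(c0[3] + span[3])] <- stats::rnorm(prod(span + 1), 60, 5)
  }
  list(vol = new_volume(vals, voxel_size = voxel_size), wm = wm)
}

# small default phantom with ten axis-aligned tubes on a 64^3 grid
ten_tube_phantom <- function(seed = 1L, contrast = 0.3, noise_sd = 0) {
  axes <- rep(1:3, length.out = 10)
  radii <- rep(c(1, 1.5, 2, 1, 2), 2)
  centers <- rbind(
    c(15, 12, 12), c(15, 32, 16), c(15, 50, 22), c(40, 14, 30),
    c(44, 32, 36), c(40, 50, 44), c(18, 14, 50), c(22, 32, 52),
    c(48, 50, 10), c(50, 12, 44))
  tubes <- lapply(seq_len(10), function(t) {
    a <- centers[t, ]; b <- centers[t, ]
    a[axes[t]] <- a[axes[t]] - 6
    b[axes[t]] <- b[axes[t]] + 6
    tube_spec(a, b, radii[t], contrast)
  })
  phantom_spec(grid_shape = c(64, 64, 64), voxel_size_mm = c(1, 1, 1),
               tubes = tubes, noise_sd = noise_sd, seed = seed)
}
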