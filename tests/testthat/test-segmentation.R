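test_that("erosion matches brute-force morphology", {
  cube <- array(FALSE, c(7, 7, 7))
  cube[2:6, 2:6, 2:6] <- TRUE
  e1 <- erode_mask(cube, 1L)
  expect_equal(sum(e1), 27)               # 5^3 cube erodes to 3^3
  expect_true(all(e1[3:5, 3:5, 3:5]))
  expect_identical(erode_mask(cube, 0L), cube)    # identity at 0 iterations
  sheet <- array(FALSE, c(6, 6, 6)); sheet[, , 3] <- TRUE
  expect_equal(sum(erode_mask(sheet, 1L)), 0)     # 1-voxel sheet vanishes
  for (seed in 1:3) {
    set.seed(seed)
    m <- array(stats::runif(6^3) > 0.4, c(6, 6, 6))
    expect_identical(erode_mask(m, 1L), naive_erode(m, 1L))
  }
  expect_error(erode_mask(array(2, c(3, 3, 3)), 1L), "binary")
})

test_that("local statistics match enumeration on a constant and a dip", {
  dims <- c(5, 5, 5)
  mask <- array(TRUE, dims)
  const <- new_volume(array(100, dims))
  st <- local_statistics(const, mask, radius_mm = 10)
  expect_true(all(st$mean_map == 100))
  expect_true(all(st$rank_map == 0))       # no neighbor strictly below
  dip <- array(100, dims); dip[3, 3, 3] <- 80
  st2 <- local_statistics(new_volume(dip), mask, radius_mm = 10)
  expect_equal(st2$mean_map[3, 3, 3], 100)          # 124 neighbors, all 100
  expect_equal(st2$rank_map[3, 3, 3], 0)
  expect_equal(st2$mean_map[1, 1, 1], mean(c(rep(100, 123), 80)))
  expect_equal(st2$rank_map[1, 1, 1], 100 * 1 / 124)
})

test_that("local statistics equal the per-voxel brute force on random fields", {
  for (seed in 1:3) {
    rv <- random_volume(c(9, 8, 10), seed)
    st <- local_statistics(rv$vol, rv$wm, radius_mm = 2)
    or <- naive_local_stats(rv$vol$data, rv$wm, c(1, 1, 1), 2)
    expect_equal(st$mean_map, or$mean_map, tolerance = 1e-12)
    expect_equal(st$rank_map, or$rank_map, tolerance = 1e-12)
  }
})

test_that("candidate rules use strict thresholds in the deficit direction", {
  dims <- c(7, 7, 7)
  mask <- array(TRUE, dims)
  base <- array(100, dims)
  # deficit of exactly 15% is NOT flagged; rank is 0 < 5 either way
  at15 <- base; at15[4, 4, 4] <- 85
  vol <- new_volume(at15)
  st <- local_statistics(vol, mask, radius_mm = 10)
  cand <- candidate_voxels(vol, mask, detection_params(), stats = st)
  expect_false(cand[4, 4, 4])
  at20 <- base; at20[4, 4, 4] <- 80       # 20% deficit -> flagged
  vol2 <- new_volume(at20)
  st2 <- local_statistics(vol2, mask, radius_mm = 10)
  cand2 <- candidate_voxels(vol2, mask, detection_params(), stats = st2)
  expect_true(cand2[4, 4, 4])
  expect_equal(sum(cand2), 1)
  # hyperintense voxels are not candidates under the one-sided reading
  bright <- base; bright[4, 4, 4] <- 140
  vol3 <- new_volume(bright)
  st3 <- local_statistics(vol3, mask, radius_mm = 10)
  expect_equal(sum(candidate_voxels(vol3, mask, detection_params(),
                                    stats = st3)), 0)
  # constant volume yields no candidates
  vol4 <- new_volume(base)
  st4 <- local_statistics(vol4, mask, radius_mm = 10)
  expect_equal(sum(candidate_voxels(vol4, mask, detection_params(),
                                    stats = st4)), 0)
})

test_that("raising the deficit bar or lowering the percentile never adds candidates", {
  rv <- random_volume(c(10, 10, 10), seed = 11)
  ew <- erode_mask(rv$wm, 1L)
  st <- local_statistics(rv$vol, rv$wm, radius_mm = 2.5)
  base <- candidate_voxels(rv$vol, ew, detection_params(
    diff_threshold = 0.10, percentile_cut = 20,
    neighborhood_radius_mm = 2.5), stats = st)
  tighter_diff <- candidate_voxels(rv$vol, ew, detection_params(
    diff_threshold = 0.20, percentile_cut = 20,
    neighborhood_radius_mm = 2.5), stats = st)
  tighter_pct <- candidate_voxels(rv$vol, ew, detection_params(
    diff_threshold = 0.10, percentile_cut = 5,
    neighborhood_radius_mm = 2.5), stats = st)
  expect_true(all(!tighter_diff | base))
  expect_true(all(!tighter_pct | base))
})

test_that("corner-to-corner connectivity joins what face connectivity splits", {
  cand <- array(FALSE, c(4, 4, 4))
  cand[1, 1, 1] <- TRUE
  cand[2, 2, 2] <- TRUE                   # shares only a corner
  lm26 <- cluster_components(cand, 26L)
  expect_equal(max(lm26$labels), 1)
  lm6 <- cluster_components(cand, 6L)
  expect_equal(max(lm6$labels), 2)
  lm18 <- cluster_components(cand, 18L)
  expect_equal(max(lm18$labels), 2)       # corner is not an edge
  empty <- cluster_components(array(FALSE, c(4, 4, 4)))
  expect_equal(max(empty$labels), 0)
})

test_that("labels are ordered by size with scan-order tie-break", {
  cand <- array(FALSE, c(10, 4, 4))
  cand[8:9, 2, 2] <- TRUE                 # 2 voxels, later in scan order
  cand[1:3, 2, 2] <- TRUE                 # 3 voxels
  cand[5, 4, 4] <- TRUE                   # singleton
  lm <- cluster_components(cand, 26L)
  expect_equal(lm$labels[1, 2, 2], 1L)
  expect_equal(lm$labels[8, 2, 2], 2L)
  expect_equal(lm$labels[5, 4, 4], 3L)
})

test_that("cluster volume filter is strict at the voxel-geometry boundary", {
  # 0.5 x 0.5 x 1.0 mm: voxel volume 0.25 mm^3; 4 voxels = 1.00 -> removed
  cand <- array(FALSE, c(12, 6, 6))
  cand[1:4, 2, 2] <- TRUE
  cand[7:11, 2, 2] <- TRUE
  lm <- cluster_components(cand, 26L, voxel_size_mm = c(0.5, 0.5, 1.0))
  fl <- filter_clusters(lm, 1.0)
  expect_equal(max(fl$labels), 1)
  expect_true(all(which(fl$labels > 0) %in% which(cand)))
  expect_equal(sum(fl$labels > 0), 5)
  # 0.94 isotropic: voxel volume 0.830584; singleton removed, pair kept
  cand2 <- array(FALSE, c(8, 6, 6))
  cand2[2, 2, 2] <- TRUE
  cand2[5:6, 2, 2] <- TRUE
  lm2 <- cluster_components(cand2, 26L, voxel_size_mm = rep(0.94, 3))
  fl2 <- filter_clusters(lm2, 1.0)
  expect_equal(max(fl2$labels), 1)
  expect_equal(sum(fl2$labels > 0), 2)
  # empty map passes through
  expect_equal(max(filter_clusters(cluster_components(
    array(FALSE, c(4, 4, 4))), 1)$labels), 0)
})

test_that("the full detector equals the brute-force rule chain", {
  for (seed in 1:4) {
    rv <- random_volume(c(12, 11, 10), seed)
    det <- detect_pvs(rv$vol, new_volume(rv$wm),
                      detection_params(neighborhood_radius_mm = 2))
    or <- naive_detect(rv$vol$data, rv$wm, c(1, 1, 1), radius_mm = 2)
    expect_identical(det$candidates, or$candidates)
    expect_identical(det$labelmap$labels, or$labels)
  }
})

test_that("every detected voxel lies inside the eroded white-matter mask", {
  rv <- random_volume(c(14, 14, 14), seed = 5)
  det <- detect_pvs(rv$vol, new_volume(rv$wm),
                    detection_params(neighborhood_radius_mm = 2.5))
  inside <- det$eroded_wm[det$labelmap$labels > 0]
  expect_true(all(inside))
  expect_true(all(det$eroded_wm[det$candidates]))
})
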