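#!/usr/bin/env Rscript
# Stage 1 — simulate every input the analysis chain consumes:
#   * a T1-like white-matter phantom with ten tubular PVS of known geometry,
#   * a DWI dataset from a piecewise-constant tensor field with known
#     projection-/association-ROI diffusivities,
#   * a two-campaign longitudinal cohort carrying the SANS-stratified
#     "No-SANS dips during bed rest, SANS flat" pattern.
# Everything is written under results/analysis/ as NIfTI / FSL text / CSV.

suppressPackageStartupMessages(library(pvsbedrest))
seed <- 20170918L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## phantom ------------------------------------------------------------------
axes <- rep(1:3, length.out = 10)
radii <- rep(c(1, 1.5, 2, 1, 2), 2)
centers <- rbind(
  c(15, 12, 12), c(15, 32, 16), c(15, 50, 22), c(40, 14, 30),
  c(44, 32, 36), c(40, 50, 44), c(18, 14, 50), c(22, 32, 52),
  c(48, 50, 10), c(50, 12, 44))
tubes <- lapply(1:10, function(t) {
  a <- centers[t, ]; b <- centers[t, ]
  a[axes[t]] <- a[axes[t]] - 6; b[axes[t]] <- b[axes[t]] + 6
  tube_spec(a, b, radii[t], contrast_fraction = 0.3)
})
ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                    voxel_size_mm = c(1, 1, 1),
                                    wm_intensity = 100, noise_sd = 0,
                                    tubes = tubes, seed = seed))
write_volume(ph$t1, file.path(out, "phantom_t1.nii.gz"))
write_volume(ph$wm_mask, file.path(out, "phantom_wm_mask.nii.gz"))
truth <- do.call(rbind, lapply(seq_along(ph$truth), function(t)
  data.frame(tube = t, radius_mm = radii[t], length_mm = 12,
             i = ph$truth[[t]][, 1], j = ph$truth[[t]][, 2],
             k = ph$truth[[t]][, 3])))
utils::write.csv(truth, file.path(out, "phantom_truth.csv"),
                 row.names = FALSE)
cat(sprintf("phantom: 10 tubes, %d ground-truth voxels\n", nrow(truth)))

## DWI ----------------------------------------------------------------------
aff <- diag(4); aff[1:3, 4] <- c(15, -18, -4)   # MNI-like world frame
tf <- array(0, c(30, 30, 30, 6))
for (c6 in 1:3) tf[, , , c6] <- 1e-3            # isotropic background
pv <- c(29, -4, 10) - aff[1:3, 4] + 1
av <- c(41, -4, 10) - aff[1:3, 4] + 1
pd <- c(1.0, 0.4, 0.9) * 1e-3                   # projection-fiber region
ad <- c(1.1, 0.9, 0.5) * 1e-3                   # association-fiber region
for (c6 in 1:3) {
  tf[(pv[1] - 3):(pv[1] + 3), (pv[2] - 3):(pv[2] + 3),
     (pv[3] - 3):(pv[3] + 3), c6] <- pd[c6]
  tf[(av[1] - 3):(av[1] + 3), (av[2] - 3):(av[2] + 3),
     (av[3] - 3):(av[3] + 3), c6] <- ad[c6]
}
dw <- generate_dwi(dwi_spec(tf, voxel_size_mm = c(1, 1, 1), affine = aff,
                            s0 = 1000, noise_sd = 0, seed = seed))
write_dwi(dw, file.path(out, "dwi"))
cat(sprintf("dwi: %d volumes (%d b0 + %d directions at b = %d)\n",
            length(dw$bvals), sum(dw$bvals == 0), sum(dw$bvals > 0),
            max(dw$bvals)))

## cohort -------------------------------------------------------------------
ep <- data.frame(metric = "median_volume_mm3",
                 timepoint = c("HDT7", "HDT29", "R+7"),
                 sans = FALSE, shift = c(-3, -3, -1.5))
tab <- generate_cohort(cohort_spec(effect_profile = ep, seed = seed))
write_cohort_csv(tab, file.path(out, "cohort.csv"))
utils::write.csv(attr(tab, "demographics"),
                 file.path(out, "cohort_demographics.csv"),
                 row.names = FALSE)
cat(sprintf("cohort: %d records, %d subjects (%d SANS)\n", nrow(tab),
            nrow(attr(tab, "demographics")),
            sum(attr(tab, "demographics")$sans)))
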