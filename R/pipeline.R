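#' Read and validate a pipeline run configuration
#'
#' A run configuration is a JSON object (or an equivalent named list) with
#' the sections `phantom`, `dwi`, `cohort`, `detection`, `alps`, `model`,
#' `out_dir` and `seed`; unknown top-level keys are rejected so that typos
#' fail loudly rather than silently falling back to defaults.
#'
#' @param config path to a JSON file, or a named list.
#' @export
read_run_config <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  stopifnot(is.list(config))
  allowed <- c("phantom", "dwi", "cohort", "detection", "alps", "model",
               "out_dir", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis chain end-to-end
#'
#' Simulate (phantom, optional DWI, cohort) -> segment -> morphometry ->
#' ALPS (when DWI is configured) -> cohort models, writing all artifacts and
#' a run-manifest JSON into `out_dir`. All randomness flows from the single
#' config seed, so a rerun with an identical config is byte-identical.
#'
#' @param config as accepted by [read_run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(seed = seed, package_version =
                     as.character(utils::packageVersion("pvsbedrest")),
                   stages = list())

  # --- simulate + segment + morph -----------------------------------------
  ph_cfg <- cfg$phantom
  summary_row <- NULL
  if (!is.null(ph_cfg)) {
    ph <- stage("simulate-phantom", {
      tubes <- lapply(ph_cfg$tubes, function(tb)
        tube_spec(unlist(tb$endpoint_a_mm), unlist(tb$endpoint_b_mm),
                  tb$radius_mm, tb$contrast_fraction))
      spec <- phantom_spec(
        grid_shape = unlist(ph_cfg$grid_shape %||% c(48, 48, 48)),
        voxel_size_mm = unlist(ph_cfg$voxel_size_mm %||% c(1, 1, 1)),
        wm_intensity = ph_cfg$wm_intensity %||% 100,
        noise_sd = ph_cfg$noise_sd %||% 0,
        tubes = tubes, seed = seed)
      generate_phantom(spec)
    })
    write_volume(ph$t1, file.path(out, "phantom_t1.nii.gz"))
    write_volume(ph$wm_mask, file.path(out, "phantom_wm_mask.nii.gz"))
    det <- stage("segment", {
      pars <- do.call(detection_params, cfg$detection %||% list())
      detect_pvs(ph$t1, ph$wm_mask, pars)
    })
    lab_vol <- new_volume(array(as.double(det$labelmap$labels),
                                dim(det$labelmap$labels)),
                          affine = ph$t1$affine)
    write_volume(lab_vol, file.path(out, "pvs_labels.nii.gz"))
    morph <- stage("morph", labelmap_metrics(det$labelmap, ph$t1$affine))
    utils::write.csv(morph, file.path(out, "pvs_clusters.csv"),
                     row.names = FALSE)
    summary_row <- subject_summary(morph, wm_volume(ph$wm_mask))
    utils::write.csv(summary_row, file.path(out, "pvs_subject_summary.csv"),
                     row.names = FALSE)
    manifest$stages$segment <- list(n_clusters = nrow(morph),
                                    n_candidates = sum(det$candidates))
  }

  # --- DWI + ALPS ----------------------------------------------------------
  if (!is.null(cfg$dwi)) {
    alps <- stage("alps", {
      dw_cfg <- cfg$dwi
      D <- if (is.null(dw_cfg$tensor)) diag(c(1.2, 0.8, 0.9)) * 1e-3
      else matrix(unlist(dw_cfg$tensor), 3, 3)
      grid <- unlist(dw_cfg$grid_shape %||% c(24, 24, 24))
      vs <- unlist(dw_cfg$voxel_size_mm %||% c(2, 2, 2))
      aff <- diag(c(vs, 1))
      aff[1:3, 4] <- c(20, -20, 0)  # MNI-like offset so ROI centers land inside
      spec <- dwi_spec(D, grid_shape = grid, voxel_size_mm = vs,
                       s0 = dw_cfg$s0 %||% 1000,
                       noise_sd = dw_cfg$noise_sd %||% 0,
                       affine = aff, seed = seed + 1L)
      dwi <- generate_dwi(spec)
      write_dwi(dwi, file.path(out, "dwi"))
      acfg <- cfg$alps %||% list()
      compute_alps(dwi,
                   proj_center = unlist(acfg$proj_center %||% c(29, -4, 10)),
                   assoc_center = unlist(acfg$assoc_center %||% c(41, -4, 10)),
                   diameter_mm = acfg$diameter_mm %||% 4)
    })
    jsonlite::write_json(list(index = alps$index, method = alps$method,
                              proj = as.list(alps$proj),
                              assoc = as.list(alps$assoc)),
                         file.path(out, "alps.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$stages$alps <- list(index = alps$index)
  } else {
    message("run_pipeline: no DWI configured; ALPS stage skipped")
  }

  # --- cohort models -------------------------------------------------------
  if (!is.null(cfg$cohort)) {
    res <- stage("cohort", {
      cspec <- cohort_spec(seed = seed + 2L)
      tab <- generate_cohort(cspec)
      write_cohort_csv(tab, file.path(out, "cohort.csv"))
      mcfg <- cfg$model %||% list()
      grouping <- mcfg$grouping %||% "sans"
      scope <- if (grouping == "sans")
        tab[tab$campaign == "HDBR+CO2", ] else tab
      do.call(rbind, lapply(unique(scope$metric), function(m)
        fit_metric_model(scope, m, mcfg$reference %||% "BDC-7",
                         grouping = grouping)))
    })
    utils::write.csv(res, file.path(out, "cohort_contrasts.csv"),
                     row.names = FALSE)
    manifest$stages$cohort <- list(n_contrasts = nrow(res))
  }

  manifest$config <- cfg
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
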