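#' Default timepoint labels per bed-rest campaign
#'
#' The HDBR campaign (60 days, ambient air) is imaged five times: 13 and 7
#' days before bed rest, days 29 and 58 within, and 10 days after. The
#' HDBR+CO2 campaign (30 days, 0.5% CO2) is imaged six times: days -13 and
#' -7, days 7 and 29 within, and recovery days +7 and +13. The two designs
#' share the BDC-7 and HDT29 sessions, which is what makes the combined
#' two-timepoint analysis possible.
#'
#' @export
default_timepoints <- function() {
  list(HDBR = c("BDC-13", "BDC-7", "HDT29", "HDT58", "R+10"),
       `HDBR+CO2` = c("BDC-13", "BDC-7", "HDT7", "HDT29", "R+7", "R+13"))
}

#' Default baseline means for the simulated metrics
#'
#' Order-of-magnitude values for a healthy adult white matter: a few hundred
#' MV-PVS in roughly 4.5e5 mm^3 of white matter gives the count density;
#' median tubule dimensions of a few mm; ALPS index in the neurotypical
#' 1.4-1.6 range.
#'
#' @export
default_baselines <- function() {
  c(pvs_count_per_mm3_wm = 6e-4,
    pvs_volume_per_mm3_wm = 2.5e-3,
    median_volume_mm3 = 5.0,
    median_length_mm = 4.0,
    median_width_mm = 1.2,
    alps_index = 1.5)
}

#' Specify a synthetic longitudinal bed-rest cohort
#'
#' Defaults reproduce the two-campaign design: 8 HDBR subjects over five
#' timepoints and 11 HDBR+CO2 subjects over six, of whom 5 develop signs of
#' SANS (all SANS cases fall in the HDBR+CO2 campaign). Sex ratios follow
#' the study demographics (HDBR 2F:6M; HDBR+CO2 5F:6M with SANS 3F:2M), and
#' ages are drawn as 34 +/- 8 years truncated to [24, 55] — demographic
#' fields exist to exercise the covariate code, not to carry effects.
#'
#' @param n_per_group named integer vector: subjects per campaign.
#' @param timepoints named list of timepoint labels per campaign.
#' @param n_sans number of SANS-labeled subjects within HDBR+CO2.
#' @param metrics metric names simulated; defaults to the five MV-PVS
#'   summaries plus the ALPS index.
#' @param baseline_means named vector of per-metric baseline means.
#' @param effect_profile `NULL` (no injected effects) or a data.frame with
#'   columns `metric`, `timepoint`, `shift` and optional `campaign` and
#'   `sans` columns (`NA` = applies to all); shifts are added to the mean of
#'   the matching records, in units of the metric's within-subject SD.
#' @param between_subject_sd,within_subject_sd variance components, in units
#'   of each metric's baseline-scaled SD (see `metric_sd_frac`).
#' @param metric_sd_frac within-subject SD of each metric as a fraction of
#'   its baseline mean (default 0.1), setting the scale of both variance
#'   components and of `shift`.
#' @param seed integer RNG seed.
#' @export
cohort_spec <- function(n_per_group = c(HDBR = 8L, `HDBR+CO2` = 11L),
                        timepoints = default_timepoints(),
                        n_sans = 5L,
                        metrics = names(default_baselines()),
                        baseline_means = default_baselines(),
                        effect_profile = NULL,
                        between_subject_sd = 1,
                        within_subject_sd = 1,
                        metric_sd_frac = 0.1,
                        seed = 1L) {
  stopifnot(all(names(n_per_group) %in% names(timepoints)))
  if (n_sans > n_per_group[["HDBR+CO2"]])
    stop("n_sans cannot exceed the HDBR+CO2 campaign size")
  if (between_subject_sd < 0 || within_subject_sd < 0)
    stop("variance components must be >= 0")
  if (!is.null(effect_profile)) {
    stopifnot(is.data.frame(effect_profile),
              all(c("metric", "timepoint", "shift") %in% names(effect_profile)))
    known_tp <- unique(unlist(timepoints))
    bad <- setdiff(unique(effect_profile$timepoint), known_tp)
    if (length(bad))
      stop(sprintf("effect_profile references unknown timepoint(s): %s",
                   paste(bad, collapse = ", ")))
  }
  structure(list(n_per_group = n_per_group, timepoints = timepoints,
                 n_sans = as.integer(n_sans), metrics = metrics,
                 baseline_means = baseline_means,
                 effect_profile = effect_profile,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 metric_sd_frac = metric_sd_frac, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_truncated_age <- function(n, mean = 34, sd = 8, lo = 24, hi = 55) {
  out <- numeric(0)
  while (length(out) < n) {
    a <- stats::rnorm(n, mean, sd)
    out <- c(out, a[a >= lo & a <= hi])
  }
  round(out[seq_len(n)], 1)
}

#' Generate a longitudinal cohort table
#'
#' Each record is `baseline + injected shift + subject intercept + residual`,
#' with the intercept shared across a subject's records of one metric and
#' the residual independent per record. Both variance components and the
#' `shift` column of the effect profile are expressed in units of the
#' metric's within-subject SD (`metric_sd_frac` times the baseline mean), so
#' an effect of 1 is a one-SD shift for every metric.
#'
#' @param spec a [cohort_spec()].
#' @return long-format data.frame with columns `subject`, `campaign`,
#'   `sans`, `sex`, `age`, `timepoint`, `metric`, `value`; a demographics
#'   table (one row per subject, with height, weight and BMI drawn from the
#'   campaign-level summary statistics) is attached as
#'   `attr(x, "demographics")`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  subjects <- list()
  for (campaign in names(spec$n_per_group)) {
    n <- spec$n_per_group[[campaign]]
    sans <- if (campaign == "HDBR+CO2")
      seq_len(n) <= spec$n_sans else rep(FALSE, n)
    sex <- if (campaign == "HDBR") {
      nf <- max(0L, round(n * 2 / 8))
      c(rep("F", nf), rep("M", n - nf))
    } else {
      c(rep(c("F", "F", "F", "M", "M"), length.out = sum(sans)),
        rep(c("F", "F", "M", "M", "M", "M"), length.out = sum(!sans)))
    }
    hw <- if (campaign == "HDBR") c(1.8, 0.1, 79.4, 12.7) else c(1.7, 0.1, 70.8, 8.6)
    height <- round(stats::rnorm(n, hw[1], hw[2]), 2)
    weight <- round(stats::rnorm(n, hw[3], hw[4]), 1)
    subjects[[campaign]] <- data.frame(
      subject = sprintf("%s_%02d", ifelse(campaign == "HDBR", "A", "V"),
                        seq_len(n)),
      campaign = campaign, sans = sans, sex = sex,
      age = draw_truncated_age(n),
      height_m = height, weight_kg = weight,
      bmi = round(weight / height^2, 1))
  }
  demo <- do.call(rbind, subjects)
  rownames(demo) <- NULL

  recs <- list()
  for (s in seq_len(nrow(demo))) {
    tps <- spec$timepoints[[demo$campaign[s]]]
    for (metric in spec$metrics) {
      base <- spec$baseline_means[[metric]]
      sd_unit <- spec$metric_sd_frac * abs(base)
      b_subj <- stats::rnorm(1, 0, spec$between_subject_sd * sd_unit)
      shift <- numeric(length(tps))
      if (!is.null(spec$effect_profile)) {
        ep <- spec$effect_profile
        for (r in seq_len(nrow(ep))) {
          if (ep$metric[r] != metric) next
          if (!is.null(ep$campaign) && !is.na(ep$campaign[r]) &&
              ep$campaign[r] != demo$campaign[s]) next
          if (!is.null(ep$sans) && !is.na(ep$sans[r]) &&
              ep$sans[r] != demo$sans[s]) next
          hit <- tps == ep$timepoint[r]
          shift[hit] <- shift[hit] + ep$shift[r] * sd_unit
        }
      }
      eps <- stats::rnorm(length(tps), 0, spec$within_subject_sd * sd_unit)
      recs[[length(recs) + 1L]] <- data.frame(
        subject = demo$subject[s], campaign = demo$campaign[s],
        sans = demo$sans[s], sex = demo$sex[s], age = demo$age[s],
        timepoint = tps, metric = metric,
        value = base + shift + b_subj + eps)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "demographics") <- demo
  out
}

#' Write / read a cohort table as CSV
#'
#' Comma-separated, UTF-8, header row, "." decimal, empty fields for
#' missing values; the demographics attribute is not serialised.
#'
#' @param table cohort data.frame.
#' @param path CSV path.
#' @name cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "campaign", "sans", "sex", "age", "timepoint",
            "metric", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("cohort CSV missing column(s): %s", paste(miss, collapse = ", ")))
  d$sans <- as.logical(d$sans)
  d
}
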