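#' One-eye ophthalmic exam record
#'
#' @param optic_disc_edema logical; any Frisen grade counts.
#' @param choroidal_folds logical.
#' @param hyperopic_shift_D hyperopic refractive shift in diopters.
#' @param globe_flattening logical.
#' @export
sans_exam <- function(optic_disc_edema = FALSE, choroidal_folds = FALSE,
                      hyperopic_shift_D = 0, globe_flattening = FALSE) {
  if (!is.finite(hyperopic_shift_D))
    stop("hyperopic_shift_D must be finite")
  structure(list(optic_disc_edema = isTRUE(optic_disc_edema),
                 choroidal_folds = isTRUE(choroidal_folds),
                 hyperopic_shift_D = hyperopic_shift_D,
                 globe_flattening = isTRUE(globe_flattening)),
            class = "sans_exam")
}

#' Classify SANS status from a pair of eye exams
#'
#' A participant shows signs of SANS if either eye presents at least one of:
#' optic disc edema (any Frisen grade), choroidal folds, globe flattening,
#' or a hyperopic refractive shift strictly greater than 0.75 D.
#'
#' @param left_eye,right_eye [sans_exam()] records.
#' @return logical SANS label.
#' @export
classify_sans <- function(left_eye, right_eye) {
  stopifnot(inherits(left_eye, "sans_exam"), inherits(right_eye, "sans_exam"))
  any(vapply(list(left_eye, right_eye), function(e)
    e$optic_disc_edema || e$choroidal_folds || e$globe_flattening ||
      e$hyperopic_shift_D > 0.75, logical(1)))
}

order_timepoints <- function(tps) {
  canonical <- c("BDC-13", "BDC-7", "HDT7", "HDT29", "HDT58", "R+7", "R+10",
                 "R+13")
  known <- intersect(canonical, tps)
  c(known, setdiff(unique(tps), canonical))
}

#' Longitudinal group-by-time linear model for one metric
#'
#' Fits `value ~ timepoint * group + sex + age_centered` by ordinary least
#' squares with timepoint as a categorical factor releveled to the
#' pre-bed-rest reference (BDC-7, the second acquisition, by default). The
#' returned contrasts are each timepoint versus the reference (within the
#' reference group) and each group-by-timepoint interaction versus the
#' reference, with model-based standard errors, two-sided p-values at
#' alpha = 0.05, and 95% confidence intervals. No multiplicity correction
#' is applied. A subject-level random intercept can be requested
#' (`method = "lmer"`) for sensitivity analyses; the default mirrors the
#' plain linear-model description of the original analysis.
#'
#' @param table long cohort data.frame (see [generate_cohort()]).
#' @param metric metric name to model.
#' @param reference_timepoint reference level for the timepoint factor.
#' @param grouping `"sans"` (SANS vs No-SANS) or `"campaign"`
#'   (HDBR+CO2 vs HDBR); the caller restricts the table to the records in
#'   scope (e.g. one campaign for the SANS stratification).
#' @param covariates include `sex` and mean-centered `age` (default TRUE).
#' @param method `"ols"` or `"lmer"` (requires lme4/lmerTest).
#' @return data.frame of contrasts: `metric`, `type` (`"time"` or
#'   `"interaction"`), `timepoint`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p`, plus `n_obs` used after listwise deletion.
#' @export
fit_metric_model <- function(table, metric, reference_timepoint = "BDC-7",
                             grouping = c("sans", "campaign"),
                             covariates = TRUE, method = c("ols", "lmer")) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  d <- table[table$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no records for metric '%s'", metric))
  d <- d[!is.na(d$value), , drop = FALSE]
  n_dropped <- sum(table$metric == metric) - nrow(d)
  if (n_dropped > 0)
    message(sprintf("fit_metric_model: %d missing records dropped (%s)",
                    n_dropped, metric))
  d$group <- if (grouping == "sans")
    factor(ifelse(d$sans, "SANS", "NoSANS"), levels = c("NoSANS", "SANS"))
  else factor(d$campaign, levels = c("HDBR", "HDBR+CO2"))
  tp_levels <- order_timepoints(d$timepoint)
  if (!reference_timepoint %in% tp_levels)
    stop(sprintf("reference timepoint '%s' not present", reference_timepoint))
  d$timepoint <- stats::relevel(factor(d$timepoint, levels = tp_levels),
                                ref = reference_timepoint)
  # every modeled group x timepoint cell needs at least two subjects
  cell <- table(d$group, d$timepoint)
  subj_cell <- tapply(d$subject, list(d$group, d$timepoint),
                      function(s) length(unique(s)))
  bad <- which(!is.na(subj_cell) & subj_cell < 2, arr.ind = TRUE)
  if (length(cell[cell > 0]) && nrow(bad))
    stop(sprintf("group x timepoint cell with < 2 subjects: %s at %s",
                 rownames(subj_cell)[bad[1, 1]],
                 colnames(subj_cell)[bad[1, 2]]))
  d$age_c <- d$age - mean(d$age)
  form <- if (covariates && length(unique(d$sex)) > 1)
    value ~ timepoint * group + sex + age_c
  else if (covariates) value ~ timepoint * group + age_c
  else value ~ timepoint * group

  if (method == "lmer") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("method = 'lmer' requires the lmerTest package")
    fit <- lmerTest::lmer(stats::update(form, . ~ . + (1 | subject)),
                          data = d)
    sm <- stats::coef(summary(fit))
    ci <- stats::confint(fit, method = "Wald")
    ci <- ci[rownames(sm), , drop = FALSE]
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    p <- sm[, "Pr(>|t|)"]
  } else {
    fit <- stats::lm(form, data = d)
    sm <- stats::coef(summary(fit))
    ci <- stats::confint(fit)
    est <- sm[, 1]; se <- sm[, 2]; p <- sm[, 4]
  }
  nm <- names(est) <- rownames(sm)
  is_time <- grepl("^timepoint", nm) & !grepl(":", nm)
  is_int <- grepl("^timepoint", nm) & grepl(":group", nm)
  tidy <- function(sel, type) {
    if (!any(sel)) return(NULL)
    tp <- sub("^timepoint", "", sub(":group.*$", "", nm[sel]))
    data.frame(metric = metric, type = type, timepoint = tp,
               estimate = unname(est[sel]), se = unname(se[sel]),
               ci_low = unname(ci[sel, 1]), ci_high = unname(ci[sel, 2]),
               p = unname(p[sel]), n_obs = nrow(d))
  }
  out <- rbind(tidy(is_time, "time"), tidy(is_int, "interaction"))
  rownames(out) <- NULL
  out
}

#' Recovery-phase contrasts
#'
#' Re-uses the model machinery of [fit_metric_model()] and returns only the
#' contrasts of the recovery timepoints against the pre-bed-rest reference.
#' Following the conditional procedure of the original analysis, recovery is
#' evaluated only when a pre- to in-bed-rest contrast is significant; set
#' `gate = FALSE` to evaluate unconditionally.
#'
#' @inheritParams fit_metric_model
#' @param recovery_timepoints character vector of recovery labels.
#' @param inbed_timepoints labels of the in-bed-rest sessions used by the
#'   gate.
#' @param gate apply the conditional procedure (default TRUE).
#' @param alpha significance level for the gate.
#' @return data.frame as in [fit_metric_model()], possibly empty (with a
#'   `gated_out` attribute when the gate closed it).
#' @export
recovery_contrasts <- function(table, metric, reference_timepoint = "BDC-7",
                               recovery_timepoints = c("R+7", "R+13"),
                               inbed_timepoints = c("HDT7", "HDT29"),
                               grouping = "sans", gate = TRUE, alpha = 0.05,
                               ...) {
  res <- fit_metric_model(table, metric, reference_timepoint,
                          grouping = grouping, ...)
  if (length(recovery_timepoints) == 0L) return(res[0, , drop = FALSE])
  if (gate) {
    inbed <- res[res$type == "time" & res$timepoint %in% inbed_timepoints, ]
    if (!any(inbed$p < alpha)) {
      out <- res[0, , drop = FALSE]
      attr(out, "gated_out") <- TRUE
      return(out)
    }
  }
  out <- res[res$timepoint %in% recovery_timepoints, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Demographic comparisons and per-metric normality checks
#'
#' Equal-variance (Student) two-sample t-tests comparing the two campaigns
#' on age, height, weight and BMI, plus a Shapiro-Wilk normality statistic
#' per metric computed on the metric's values.
#'
#' @param table cohort data.frame with a `demographics` attribute, or NULL
#'   `demographics` supplied directly.
#' @param demographics per-subject data.frame with `campaign`, `age`,
#'   `height_m`, `weight_kg`, `bmi`.
#' @return list with `t_tests` (data.frame: variable, t, df, p, mean per
#'   group) and `shapiro` (data.frame: metric, W, p).
#' @export
demographics_tests <- function(table = NULL,
                               demographics = attr(table, "demographics")) {
  if (is.null(demographics))
    stop("no demographics table available")
  g <- split(demographics, demographics$campaign)
  if (length(g) != 2L) stop("exactly two campaigns are required")
  if (any(vapply(g, nrow, integer(1)) < 3L))
    stop("each campaign needs at least 3 subjects for the t-tests")
  vars <- c(age = "age", height = "height_m", weight = "weight_kg",
            bmi = "bmi")
  tt <- do.call(rbind, lapply(names(vars), function(v) {
    col <- vars[[v]]
    ht <- stats::t.test(g[[1]][[col]], g[[2]][[col]], var.equal = TRUE)
    data.frame(variable = v, t = unname(ht$statistic),
               df = unname(ht$parameter), p = ht$p.value,
               mean_1 = unname(ht$estimate[1]), mean_2 = unname(ht$estimate[2]),
               group_1 = names(g)[1], group_2 = names(g)[2])
  }))
  sw <- NULL
  if (!is.null(table)) {
    sw <- do.call(rbind, lapply(split(table$value, table$metric), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 3 || length(unique(v)) == 1L)
        return(data.frame(W = NA_real_, p = NA_real_))
      s <- stats::shapiro.test(v)
      data.frame(W = unname(s$statistic), p = s$p.value)
    }))
    sw <- data.frame(metric = rownames(sw), sw, row.names = NULL)
  }
  list(t_tests = tt, shapiro = sw)
}
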