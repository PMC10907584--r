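co2_table <- function(spec) {
  tab <- generate_cohort(spec)
  tab[tab$campaign == "HDBR+CO2", , drop = FALSE]
}

test_that("SANS labeling follows the either-eye any-sign rule", {
  clear <- sans_exam()
  # edema in one eye only is enough
  expect_true(classify_sans(sans_exam(optic_disc_edema = TRUE), clear))
  expect_true(classify_sans(clear, sans_exam(choroidal_folds = TRUE)))
  expect_true(classify_sans(clear, sans_exam(globe_flattening = TRUE)))
  # no signs, zero shift in both eyes
  expect_false(classify_sans(clear, clear))
  # hyperopic shift: strictly greater than 0.75 D
  expect_true(classify_sans(clear, sans_exam(hyperopic_shift_D = 0.80)))
  expect_false(classify_sans(clear, sans_exam(hyperopic_shift_D = 0.75)))
  expect_error(sans_exam(hyperopic_shift_D = Inf), "finite")
})

test_that("model output is tidy with CI containing the estimate", {
  tab <- co2_table(cohort_spec(seed = 21))
  res <- fit_metric_model(tab, "alps_index")
  expect_setequal(unique(res$type), c("time", "interaction"))
  # five non-reference timepoints in each family
  expect_equal(sum(res$type == "time"), 5)
  expect_equal(sum(res$type == "interaction"), 5)
  expect_false("BDC-7" %in% res$timepoint)   # reference has no contrast row
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("refitting after a reference relabel round-trip is invariant", {
  tab <- co2_table(cohort_spec(seed = 22))
  res1 <- fit_metric_model(tab, "median_width_mm")
  # permute record order; the model must not care
  tab2 <- tab[rev(seq_len(nrow(tab))), ]
  res2 <- fit_metric_model(tab2, "median_width_mm")
  expect_equal(res1$estimate, res2$estimate, tolerance = 1e-10)
  expect_equal(res1$p, res2$p, tolerance = 1e-10)
  # a different reference then back reproduces the original contrasts
  res3 <- fit_metric_model(tab, "median_width_mm",
                           reference_timepoint = "HDT29")
  expect_false(isTRUE(all.equal(sort(res1$estimate), sort(res3$estimate))))
  res4 <- fit_metric_model(tab, "median_width_mm",
                           reference_timepoint = "BDC-7")
  expect_equal(res1, res4)
})

test_that("an injected group-by-time shift is recovered within 3 SE", {
  delta <- 1.0
  ep <- data.frame(metric = "median_volume_mm3", timepoint = "HDT29",
                   sans = TRUE, shift = delta)
  sp <- cohort_spec(n_per_group = c(`HDBR+CO2` = 400L), n_sans = 200L,
                    metrics = "median_volume_mm3", effect_profile = ep,
                    between_subject_sd = 0, seed = 31)
  tab <- co2_table(sp)
  res <- fit_metric_model(tab, "median_volume_mm3")
  row <- res[res$type == "interaction" & res$timepoint == "HDT29", ]
  sd_unit <- 0.1 * default_baselines()[["median_volume_mm3"]]
  expect_lt(abs(row$estimate - delta * sd_unit), 3 * row$se)
  expect_lt(row$p, 0.001)
  # other interaction contrasts stay null at 3 SE
  others <- res[res$type == "interaction" & res$timepoint != "HDT29", ]
  expect_true(all(abs(others$estimate) < 3 * others$se))
})

test_that("type-I error of the interaction tests is near nominal", {
  reps <- 250
  ps <- unlist(lapply(seq_len(reps), function(s) {
    tab <- co2_table(cohort_spec(metrics = "alps_index",
                                 between_subject_sd = 0, seed = 1000 + s))
    res <- fit_metric_model(tab, "alps_index")
    res$p[res$type == "interaction"]
  }))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("sparse group cells are reported by name", {
  sp <- cohort_spec(n_per_group = c(`HDBR+CO2` = 6L), n_sans = 1L, seed = 3,
                    metrics = "alps_index")
  tab <- co2_table(sp)
  expect_error(fit_metric_model(tab, "alps_index"), "< 2 subjects")
})

test_that("recovery contrasts follow the conditional gating procedure", {
  # effect during bed rest that fully resolves at recovery
  ep <- data.frame(metric = "alps_index",
                   timepoint = c("HDT7", "HDT29"), sans = NA,
                   shift = c(-3, -3))
  sp <- cohort_spec(n_per_group = c(`HDBR+CO2` = 80L), n_sans = 40L,
                    metrics = "alps_index", effect_profile = ep,
                    between_subject_sd = 0, seed = 41)
  tab <- co2_table(sp)
  rec <- recovery_contrasts(tab, "alps_index", gate = TRUE)
  expect_true(all(rec$timepoint %in% c("R+7", "R+13")))
  expect_equal(sum(rec$type == "time"), 2)
  time_rows <- rec[rec$type == "time", ]
  expect_true(all(abs(time_rows$estimate) < 3 * time_rows$se))
  # persistent effect: recovery contrast recovers the injected magnitude
  ep2 <- rbind(ep, data.frame(metric = "alps_index",
                              timepoint = c("R+7", "R+13"), sans = NA,
                              shift = c(-3, -3)))
  sp2 <- cohort_spec(n_per_group = c(`HDBR+CO2` = 80L), n_sans = 40L,
                     metrics = "alps_index", effect_profile = ep2,
                     between_subject_sd = 0, seed = 42)
  rec2 <- recovery_contrasts(co2_table(sp2), "alps_index", gate = FALSE)
  sd_unit <- 0.1 * default_baselines()[["alps_index"]]
  t2 <- rec2[rec2$type == "time", ]
  expect_true(all(abs(t2$estimate - (-3 * sd_unit)) < 3 * t2$se))
  # no injected effect anywhere: the gate closes recovery testing
  sp0 <- cohort_spec(n_per_group = c(`HDBR+CO2` = 40L), n_sans = 20L,
                     metrics = "alps_index", between_subject_sd = 0,
                     seed = 43)
  rec0 <- recovery_contrasts(co2_table(sp0), "alps_index", gate = TRUE)
  if (nrow(rec0) == 0) expect_true(isTRUE(attr(rec0, "gated_out")))
  # empty recovery list gives an empty result
  rec_empty <- recovery_contrasts(tab, "alps_index",
                                  recovery_timepoints = character(0))
  expect_equal(nrow(rec_empty), 0)
})

test_that("demographic t-tests match the pooled-variance closed form", {
  # fixed synthetic 4-vs-4 toy table shipped as a plain-text fixture
  toy <- utils::read.csv(test_path("fixtures", "ttest_toy_synthetic.csv"))
  g1 <- toy$value[toy$group == "A"]; g2 <- toy$value[toy$group == "B"]
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  demo <- data.frame(campaign = toy$group, age = toy$value,
                     height_m = toy$value / 50, weight_kg = toy$value,
                     bmi = toy$value / 3)
  res <- demographics_tests(demographics = demo)
  expect_equal(res$t_tests$t[res$t_tests$variable == "age"], t_hand,
               tolerance = 1e-12)
  expect_equal(res$t_tests$df[1], n1 + n2 - 2)
  # identical groups: t = 0, p = 1
  demo2 <- demo; demo2$campaign <- rep(c("A", "B"), each = 4)
  demo2$age <- rep(c(30, 35, 40, 45), 2)
  demo2$height_m <- rep(c(1.6, 1.7, 1.8, 1.9), 2)
  demo2$weight_kg <- rep(c(60, 70, 80, 90), 2)
  demo2$bmi <- rep(c(20, 22, 24, 26), 2)
  res2 <- demographics_tests(demographics = demo2)
  expect_equal(res2$t_tests$t[res2$t_tests$variable == "age"], 0)
  expect_equal(res2$t_tests$p[res2$t_tests$variable == "age"], 1)
  expect_error(demographics_tests(
    demographics = demo[c(1, 2, 5, 6), ]), "at least 3")
})

test_that("Shapiro-Wilk statistics are reported per metric", {
  tab <- generate_cohort(cohort_spec(seed = 51))
  res <- demographics_tests(tab)
  expect_setequal(res$shapiro$metric, names(default_baselines()))
  expect_true(all(res$shapiro$W > 0 & res$shapiro$W <= 1))
})
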