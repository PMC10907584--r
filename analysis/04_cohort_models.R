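#!/usr/bin/env Rscript
# Stage 4 — longitudinal SANS-stratified statistics on the stage-1 cohort.
# For each metric: the group-by-time linear model against the pre-bed-rest
# reference (BDC-7), recovery contrasts under the conditional gate, plus
# campaign demographics t-tests and Shapiro-Wilk normality checks.

suppressPackageStartupMessages(library(pvsbedrest))
out <- "results/analysis"
tab <- read_cohort_csv(file.path(out, "cohort.csv"))
demo <- utils::read.csv(file.path(out, "cohort_demographics.csv"))

co2 <- tab[tab$campaign == "HDBR+CO2", ]
metrics <- unique(co2$metric)
contrasts <- do.call(rbind, lapply(metrics, function(m)
  fit_metric_model(co2, m, grouping = "sans")))
utils::write.csv(contrasts, file.path(out, "cohort_contrasts.csv"),
                 row.names = FALSE)

rec <- do.call(rbind, lapply(metrics, function(m)
  recovery_contrasts(co2, m, grouping = "sans", gate = TRUE)))
utils::write.csv(rec, file.path(out, "recovery_contrasts.csv"),
                 row.names = FALSE)

# combined-cohort view: the two campaigns share BDC-7 and HDT29 only
shared <- tab[tab$timepoint %in% c("BDC-7", "HDT29"), ]
combined <- do.call(rbind, lapply(metrics, function(m)
  fit_metric_model(shared, m, grouping = "sans")))
utils::write.csv(combined, file.path(out, "combined_cohort_contrasts.csv"),
                 row.names = FALSE)

dt <- demographics_tests(tab, demographics = demo)
utils::write.csv(dt$t_tests, file.path(out, "demographics_ttests.csv"),
                 row.names = FALSE)
utils::write.csv(dt$shapiro, file.path(out, "shapiro_normality.csv"),
                 row.names = FALSE)

cat(sprintf("fitted %d contrasts across %d metrics\n", nrow(contrasts),
            length(metrics)))
sig_t <- contrasts[contrasts$type == "time" & contrasts$p < 0.05, ]
cat("timepoint contrasts vs BDC-7 with p < 0.05:\n")
if (nrow(sig_t)) {
  print(sig_t[c("metric", "timepoint", "estimate", "p")], row.names = FALSE)
} else {
  cat("  none\n")
}
trend_i <- contrasts[contrasts$type == "interaction" & contrasts$p < 0.10, ]
cat("SANS x timepoint interactions with p < 0.10:\n")
if (nrow(trend_i)) {
  print(trend_i[c("metric", "timepoint", "estimate", "p")], row.names = FALSE)
} else {
  cat("  none\n")
}
cat(sprintf("recovery contrasts evaluated for %d metric(s) (gated)\n",
            length(unique(rec$metric))))
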