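#!/usr/bin/env Rscript
# Step 4 — cohort statistics.
#
# Reproduces the study's statistical analyses on the simulated cohort:
# the demographics/biomarker group summary (ANOVA + Fisher LSD, chi-square
# for sex), the per-shell Pearson regressions of ALPS on MMSE, centiloid
# and VSRAD, and the normalized-slope comparison of nDTI-ALPS, nVSRAD and
# nMMSE against centiloid. Figures are drawn when ggplot2 is available.

suppressPackageStartupMessages(library(glymalps))

out <- "results/analysis"
cohort <- read.table(file.path(out, "cohort.tsv"), header = TRUE,
                     sep = "\t")
cohort$group <- factor(cohort$group, levels = c("CN", "AD"))

t1 <- group_summary_table(cohort)
write.table(t1, file.path(out, "group_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("group summary (mean ± SD, ANOVA p):")
print(t1, row.names = FALSE)

t2 <- regression_table(cohort)
write.table(t2, file.path(out, "regressions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cl <- t2[t2$predictor == "centiloid", ]
message(sprintf(
  "ALPS ~ centiloid: slope %.5f (b1000) / %.5f (b2000), r %.2f / %.2f",
  cl$slope[cl$response == "ALPS_b1000"],
  cl$slope[cl$response == "ALPS_b2000"],
  cl$r[cl$response == "ALPS_b1000"], cl$r[cl$response == "ALPS_b2000"]))

t4 <- normalized_slope_analysis(cohort)
write.table(t4, file.path(out, "normalized_slopes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
k <- attr(t4, "constants")
message(sprintf(
  "normalized slopes vs centiloid (ALPS_MAX %.3f): nDTI-ALPS %.3f, nVSRAD %.3f, nMMSE %.3f",
  k$ALPS_MAX, t4$slope[t4$biomarker == "nDTI_ALPS"],
  t4$slope[t4$biomarker == "nVSRAD"],
  t4$slope[t4$biomarker == "nMMSE"]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  fit <- pearson_regression(cohort$centiloid, cohort$ALPS_b1000)
  band <- confidence_band(fit, seq(min(cohort$centiloid),
                                   max(cohort$centiloid), length.out = 80))
  p1 <- ggplot(cohort, aes(centiloid, ALPS_b1000, shape = group)) +
    geom_point() +
    geom_line(data = band, aes(x, fit), inherit.aes = FALSE) +
    geom_line(data = band, aes(x, lwr), linetype = 2,
              inherit.aes = FALSE) +
    geom_line(data = band, aes(x, upr), linetype = 2,
              inherit.aes = FALSE) +
    labs(x = "PiB centiloid", y = "DTI-ALPS (b = 1000)",
         title = sprintf("ALPS vs amyloid burden (r = %.2f)", fit$r)) +
    theme_minimal()
  ggsave(file.path(out, "fig_alps_vs_centiloid.pdf"), p1,
         width = 5, height = 4)

  norm <- normalize_biomarkers(cohort)
  long <- rbind(
    data.frame(centiloid = norm$centiloid, value = norm$nDTI_ALPS,
               biomarker = "nDTI-ALPS"),
    data.frame(centiloid = norm$centiloid, value = norm$nVSRAD,
               biomarker = "nVSRAD"),
    data.frame(centiloid = norm$centiloid, value = norm$nMMSE,
               biomarker = "nMMSE"))
  p2 <- ggplot(long, aes(centiloid, value, shape = biomarker)) +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", se = FALSE, linewidth = 0.4,
                aes(group = biomarker)) +
    labs(x = "PiB centiloid", y = "normalized biomarker (0-100)") +
    theme_minimal()
  ggsave(file.path(out, "fig_normalized_biomarkers.pdf"), p2,
         width = 5.5, height = 4)
  message("wrote figures to ", out)
}
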