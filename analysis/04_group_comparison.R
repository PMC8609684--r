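#!/usr/bin/env Rscript
# Stage 4: group statistics.
#
# Reproduces the nonparametric comparison protocol on the per-animal
# estimates: exact Mann-Whitney U for every between-group (Tg vs non-Tg)
# contrast with percent changes; Friedman rank ANOVA across the principal
# cell layers within each group, with exact Wilcoxon signed-rank post-hocs
# when the omnibus passes; and a publication-style mean +/- SD summary.

library(stereovasc)

est <- read.csv("results/estimates.csv")
report <- build_report(est, reference_group = "nonTg", alpha = 0.05)
write_report(report, "results/report")

print(report)

bg <- report$between_group
key <- bg[bg$compartment == "DG" & bg$parameter == "l_m", ]
message(sprintf(
  "\nHeadline contrast -- DG total capillary length: %+d%% (U = %g, p = %.4f)",
  key$percent_change, key$u, key$p_value))
key2 <- bg[bg$compartment == "total" & bg$parameter == "mean_len_um", ]
message(sprintf(
  "Whole-region mean capillary length: %+d%% (U = %g, p = %.4f)",
  key2$percent_change, key2$u, key2$p_value))

wg <- report$within_group
if (!is.null(wg)) {
  message("\nWithin-group Friedman omnibus (PCL compartments):")
  for (i in seq_len(nrow(wg))) {
    message(sprintf("  %s / %s: chi^2 = %.2f, p = %.3f%s",
                    wg$group[i], wg$parameter[i], wg$friedman_chisq[i],
                    wg$friedman_p[i],
                    if (wg$friedman_p[i] <= 0.05) " -> post-hoc Wilcoxon run"
                    else ""))
  }
}
message("\nWrote results/report_summary.csv, results/report_between_group.csv, results/report.json")
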