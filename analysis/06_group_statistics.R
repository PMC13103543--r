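#!/usr/bin/env Rscript
# Stage 6: group statistics.
#
# Case-control Welch t battery with BH-FDR and Hedges g over the 7 temporal
# metrics and the 6 pairwise transitions; covariate-adjusted linear models
# (age, sex, mean FD, site); medication/episode stratification; and the
# within-subject state-FC repeated-measures ANOVA with Greenhouse-Geisser
# correction plus FDR-corrected paired post-hocs. Also recomputes the
# published inferential battery from the shipped reference summaries for
# side-by-side comparison.

suppressMessages(library(dfcstates))

cohort <- read_metadata("results/cohort/metadata.tsv")
metrics <- read_table("results/metrics.tsv")
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

temporal_cols <- c("transitions", paste0("occupancy_s", 1:3),
                   paste0("dwell_s", 1:3))
pair_cols <- grep("^t_[0-9]to[0-9]$", colnames(metrics), value = TRUE)

temporal <- group_battery(metrics, cohort, temporal_cols, adjusted = TRUE)
write_table(temporal, "results/stats/temporal.tsv")
cat("Temporal battery (control-minus-patient t, BH q):\n")
print(temporal[, c("metric", "t", "df", "p", "q", "g")], digits = 3)

transitions <- group_battery(metrics, cohort, pair_cols)
write_table(transitions, "results/stats/transitions.tsv")

for (strat in c("medication", "episode")) {
  if (any(!is.na(cohort[[strat]]))) {
    res <- stratified_compare(metrics, cohort, strat, temporal_cols,
                              adjusted = TRUE)
    write_table(res, sprintf("results/stats/stratified_%s.tsv", strat))
  }
}

fc_mat <- as.matrix(metrics[, paste0("fc_s", 1:3)])
anova_res <- rm_anova_gg(fc_mat)
write_table(as.data.frame(anova_res), "results/stats/state_fc_anova.tsv")
posthoc <- paired_posthoc(fc_mat, names = paste0("fc_s", 1:3))
write_table(posthoc, "results/stats/state_fc_posthoc.tsv")
cat(sprintf("\nState FC ANOVA: F(%.2f, %.2f) = %.1f, p = %.2g, GG eps = %.2f\n",
            anova_res$df1, anova_res$df2, anova_res$F, anova_res$p,
            anova_res$epsilon))
cat(sprintf("Post-hoc max q: %.2g (all pairs distinct below 0.001: %s)\n",
            max(posthoc$q), all(posthoc$q < 0.001)))

ref <- summary_battery(reference_summaries("temporal"))
write_table(ref, "results/stats/reference_battery.tsv")
cat("\nPublished-summary battery (recomputed t/df/q/g):\n")
print(ref[, c("metric", "t", "df", "q", "g")], digits = 3)
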