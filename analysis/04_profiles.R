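#!/usr/bin/env Rscript
# Stage 4 — each rater's operative grading criterion, from the
# isolated-nuclei (2x5 matrix) trials of the study-scale cohort: Spearman
# correlations of the 40 matrix grades against the displays' mean
# features, the strongest feature passing |rho| > 0.3 and p < 0.05, and
# the grade-vs-feature regression slope used for bias attribution.

suppressPackageStartupMessages(library(gazegrade))

matrix_grades <- read_table_gg("results/cohort_full/matrix_grades.csv")
matrix_features <- read_table_gg("results/cohort_full/matrix_features.csv")

pr <- profile_cohort(matrix_grades, matrix_features)
write_table_gg(pr$selection, "results/rater_profiles.csv")
write_table_gg(pr$correlations, "results/rater_correlations.csv")

sel <- pr$selection
tab <- table(ifelse(is.na(sel$preferred_feature), "none",
                    sel$preferred_feature))
cat("preferred grading criterion per rater:\n")
print(tab)
drv <- sel[!is.na(sel$preferred_feature), ]
cat(sprintf("median |rho| among feature-driven raters: %.2f\n",
            median(abs(drv$rho))))
for (f in unique(drv$preferred_feature)) {
  cat(sprintf("  %s: median slope %.3g grade units per feature unit (n=%d)\n",
              f, median(drv$slope[drv$preferred_feature == f]),
              sum(drv$preferred_feature == f)))
}
cat("profiles written to results/rater_profiles.csv\n")
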