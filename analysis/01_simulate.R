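#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic experiment.
#
# Two artifacts:
#  * results/cohort_full/  — the study-scale cohort (20 carcinomas x 2
#    architectural conditions x 20 raters) as analysis tables, using the
#    generator's fixation ground truth directly. This is what the
#    statistical stages (04, 05) consume.
#  * results/cohort_demo/  — a small fully-rendered cohort (4 cases x 3
#    raters, 500 px fields) with pixel rasters and 50 Hz gaze logs, for
#    the imaging stages (02, 03) that exercise the raster/gaze layers.

suppressPackageStartupMessages(library(gazegrade))

seed <- 1L

cfg_full <- cohort_config(seed = seed)
sim <- simulate_cohort(cfg_full)
dir.create("results/cohort_full", recursive = TRUE, showWarnings = FALSE)
write_table_gg(sim$fields, "results/cohort_full/fields.csv")
write_table_gg(sim$nuclei, "results/cohort_full/nuclei.csv")
fx <- sim$fixated; names(fx)[names(fx) == "label"] <- "nucleus_label"
write_table_gg(fx, "results/cohort_full/fixations.csv")
g <- sim$grades; g$latent <- NULL
write_table_gg(g, "results/cohort_full/grades.csv")
write_table_gg(sim$matrix_grades, "results/cohort_full/matrix_grades.csv")
write_table_gg(sim$matrix_features, "results/cohort_full/matrix_features.csv")
write_manifest(cfg_full, "results/cohort_full/manifest.yaml")

cat(sprintf("study-scale cohort: %d raters x %d cases x 2 conditions, %d nuclei\n",
            cfg_full$n_raters, cfg_full$n_cases, nrow(sim$nuclei)))

cfg_demo <- cohort_config(
  n_cases = 4, n_raters = 3, nuclei_per_field = 24,
  field_diameter_px = 500, size_mean = 800, size_sd_within = 220,
  size_sd_case = 150, min_saccade_px = 100,
  slopes = c(size_px = 1.6e-3, hyperchromasia = -0.03,
             heterochromasia = 0.06, roundness = -2),
  rater_features = c("size_px", "hyperchromasia", "none"),
  seed = seed)
demo <- simulate_cohort_files(cfg_demo, "results/cohort_demo")
cat(sprintf("rendered demo cohort: %d fields (%d px), %d gaze logs under results/cohort_demo\n",
            nrow(demo$fields), cfg_demo$field_diameter_px,
            length(demo$streams)))
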