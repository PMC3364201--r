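# gazegrade

Nuclear grading in histopathology is supposed to score nuclear atypia
alone, yet the surrounding tumor architecture biases it: when the same
high-power field (HPF) of a prostate carcinoma is graded once after a
tubule-rich (Gleason 2–3) low-power prime and once after a solid
(Gleason 4–5) prime, raters systematically assign higher nuclear grades
under the solid prime. `gazegrade` implements the analysis chain that
asks how much of that bias is mediated by *which nuclei the rater looks
at*:

* **Nuclear morphometry** — per-nucleus `size_px` (area),
  `hyperchromasia` (mean grey, lower = darker), `heterochromasia`
  (grey-level SD) and `roundness` (form factor 4πA/P², Crofton
  perimeter) from labeled masks over grey/RGB rasters.
* **Gaze analysis** — dispersion-threshold (I-DT) fixation detection on
  50 Hz gaze logs (minimum 100 ms) and fixation-to-nucleus assignment.
* **Rater profiles** — Spearman identification of each rater's operative
  grading criterion from isolated-nuclei 2×5 matrix trials (|ρ| > 0.3,
  p < 0.05, strongest feature wins) and the grade-vs-feature OLS slope β.
* **Bias decomposition** — per rater, the selection-predicted grade
  shift β·(f̄_solid − f̄_tubular) over the fixated nuclei, divided by the
  observed grade delta: the *fraction of the bias explained by selective
  fixation*.
* **Synthetic cohort generator** — rendered histology-like HPFs, gaze
  streams and grades with complete ground truth, so the whole pipeline
  is verifiable end to end without human-subject data.

## Worked example

The `analysis/` scripts run the full study on a synthetic cohort:
`01_simulate.R` generates a study-scale cohort (20 raters × 20 carcinomas
× 2 conditions, seed 1) plus a small fully-rendered cohort;
`02_morphometry.R` and `03_fixations.R` exercise the raster and gaze
layers; `04_profiles.R` and `05_bias.R` produce the statistics. Stage 5
prints:

```
Architecture-induced grade bias (20 raters)
  tubular 2.01 +/- 0.15, solid 2.37 +/- 0.22
  mean delta 0.362; paired t(19) = 11.47, p = 5.51e-10

Fixated-feature shifts (solid - tubular):
         feature mean_tubular mean_solid     shift       t         p
         size_px    3191.7241   3276.664 84.940157  4.7094 0.0001526
  hyperchromasia     134.4114    134.239 -0.172203 -0.6147 0.5460192
 heterochromasia      45.2768     45.176 -0.101160 -1.3476 0.1936245
       roundness       0.8816      0.884  0.002418  2.1009 0.0492289

Selection-explained fraction of the grade bias (20 raters)
  mean 8.6%, median 6.1%, range -1.0%-23.3%
  note: 1 fraction(s) outside [0%, 100%]
```

Reading: every rater grades the same fields ~0.36 grade units higher
under the solid prime (paired t across 20 raters); raters fixate larger
nuclei under the solid prime (+85 px here; only the size shift is
expected in this synthetic cohort because features are generated
independently); but propagating each rater's own grading slope through
their fixated-feature shift predicts only ~9% of the observed bias —
selective fixation vindicates, rather than produces, the architectural
pull. Per-rater tables land in `results/decomposition.csv`, a structured
report in `results/report.txt`.

The same machinery is available programmatically:

```r
library(gazegrade)
cfg <- cohort_config(seed = 1)       # study-scale defaults
sim <- simulate_cohort(cfg)
res <- analyze_cohort(sim)
res$decomposition$summary
```

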