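---
title: "Decomposing the architectural bias on nuclear grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the architectural bias on nuclear grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazegrade)
```

## The problem

Nuclear grade is meant to score nuclear atypia on its own: small, pale,
round nuclei at one end of a 1–3 scale (half steps allowed), large, dark,
angulated nuclei at the other. In prostate carcinoma, however, the
low-power *architecture* of the tumor — tubule-rich (Gleason 2–3) versus
solid (Gleason 4–5) — primes the grader, and nuclear grades gravitate
towards the architectural impression. When the same high-power field
(HPF) is graded once after a tubule-rich prime and once after a solid
prime, every rater assigns systematically higher grades under the solid
prime.

One candidate mechanism is *selective fixation*: a primed rater may look
at the nuclei that match the expectation — bigger and darker ones under a
solid prime — so that the graded evidence itself is biased. Eye tracking
makes this measurable. This package implements the full analysis chain
that separates the two routes:

1. **Morphometry.** Each nucleus in an HPF gets four features from its
   labeled mask over the grey image: `size_px` (pixel count),
   `hyperchromasia` (mean grey level; lower = darker),
   `heterochromasia` (SD of the grey-level histogram), and `roundness`
   (form factor $4\pi A / P^2$, 1 for a circle, around 0.6 for highly
   angulated contours).
2. **Gaze.** Fixations are detected from 50 Hz gaze samples with the
   dispersion-threshold algorithm (I-DT) and mapped onto nuclei; a
   nucleus counts as *inspected* when fixated for at least 100 ms.
3. **Rater profiles.** In separate trials, ten nuclei per HPF are shown
   isolated in a 2×5 matrix, outside any architectural context, and
   graded. Spearman correlations of these grades against the displays'
   mean features identify each rater's operative criterion (threshold
   $|\rho| > 0.3$, $p < 0.05$; strongest passing feature wins; absolute
   values so that darkness, a negative correlation with grey level,
   qualifies). An OLS regression of matrix grade on that feature gives
   the rater's personal grade-per-feature-unit slope $\beta$.
4. **Decomposition.** For each rater, the grade shift *predicted from
   selection alone* is $\hat\Delta = \beta \cdot (\bar f_{\mathrm{solid}}
   - \bar f_{\mathrm{tubular}})$, where $\bar f_c$ is the mean preferred
   feature of the nuclei the rater actually fixated under condition $c$.
   The *fraction explained* is $\hat\Delta / \Delta_{\mathrm{obs}}$ with
   $\Delta_{\mathrm{obs}}$ the rater's observed grade delta. The unit of
   inference is the rater throughout (20 raters give df = 19 in every
   paired test), matching the experimental design in which each rater
   grades every carcinoma under both primes.

Because the original eye-tracking and grading records were never
deposited, the package ships a synthetic cohort generator with complete
ground truth; every stage, and the end-to-end decomposition, is verified
against that truth.

## Numerical choices in the morphometry

**Perimeter.** The form factor needs a perimeter estimate on a raster
mask. Counting boundary pixels or measuring the midpoint
marching-squares polygon overestimates the length of diagonal runs (a
disc comes out with a form factor near 0.91), so the package uses the
4-direction Crofton estimator from integral geometry: boundary length is
recovered from intercept counts over all 2×2 pixel configurations with
the standard coefficient table. A disc of radius 100 px yields a form
factor of 0.9945, radius 200 px 0.9984, converging to the theoretical 1;
the estimator is exactly invariant under 90° rotations and mirror flips.
Discretization can still push tiny regions above 1, so values are
clamped to 1.0 (the scale's bound) with a debug log entry. The test
suite cross-checks against an independent route: Moore contour tracing
with Vossepoel–Smeulders corrected chain-code lengths.

**Other conventions.** RGB input is converted to luminance
(0.299/0.587/0.114) before any histogram statistic. `heterochromasia`
uses the population SD (divide by $N$), matching a read-off from a
histogram of all mask pixels; the sample SD is available via
`sd_type = "sample"`. Coordinates are (row, col), 0-based, origin at the
top-left pixel center. Regions under 20 px are dropped (form factor is
meaningless there); the threshold is configurable.

## Numerical choices in the gaze stage

The minimum fixation duration (100 ms) and the tracker geometry (50 Hz,
0.4° accuracy) are fixed by the experimental setup. Two quantities are
not documented by the original toolchain and are explicit parameters
here:

* `dispersion_px = 40` — the I-DT dispersion threshold (bounding-box
  width + height), about 1° of visual angle at the study geometry where
  0.4° spans roughly 14 px. This is standard I-DT practice; the
  detector's sensitivity to it is itself tested.
* `assignment_radius_px = 14` — how far outside a mask a fixation
  centroid may fall and still be attributed to that nucleus, the pixel
  equivalent of the tracker's 0.4° accuracy.

Duration is counted inclusive of one trailing sample interval, so
exactly five samples at 50 Hz span 100 ms and pass the threshold.
Invalid samples split candidate windows; nothing is interpolated.
Fixated-nucleus aggregation counts each nucleus once per trial
(`weight = "duration"` switches to dwell-weighted means, since the
original analysis does not document which was used). Aggregation to the
rater × condition level is two-stage — per-field means over the distinct
fixated nuclei, then an equal-weight mean across fields — which keeps
the aggregate commensurate with per-trial grade means: on noiseless
data, predicted and observed deltas then coincide exactly, a property
the test suite asserts at 10⁻⁶.

The profile thresholds are read as $|\rho| > 0.3$ and $p < 0.05$.
Exact $|\rho|$ ties break by the fixed order size, hyperchromasia,
roundness, heterochromasia. The attribution regression is univariate on
the strongest feature; for raters correlating with two features no
bivariate model is attempted. The decomposition defaults to per-rater
aggregate feature shifts; `mode = "per_pair"` computes the predicted
delta per case pair and averages, since the original aggregation level
is not documented. Raters with no qualifying feature contribute a
predicted delta of 0 (and hence fraction 0); raters with an observed
delta of exactly 0 are excluded from the cohort summary with a logged
note. Fractions are reported unclipped — under noise they can be
negative or exceed 100% — and the summary counts values outside [0, 1].

## What the synthetic cohort emulates

`cohort_config()` defaults encode the study conditions: 20 carcinomas ×
2 architectural conditions × 20 raters; 8-second trials at 50 Hz; 1704 px
circular HPFs; ten isolated nuclei per matrix display; grades on the
half-step 1–3 scale (quarter-step ties round half-up); a rater mix of 11
size-driven, 4 darkness-driven and 5 criterion-free graders per 20,
echoing the reported cohort composition.

Where the study fixes only outcomes, the generator is calibrated once to
reproduce that regime and the values are not revisited: tubular-condition
mean grade 2.02 and solid 2.42 (delta 0.40); nuclear size log-normal with
mean 3200 px and within-field SD 900 px; mean grey 134 with per-nucleus
SD 45; a selection tilt (`selection_strength = 0.062`, the exponential
tilt per within-field SD of the rater's selection feature) that shifts
the fixated size mean by ≈111 px between conditions; a generative size
slope of 4 × 10⁻⁴ grade/px so selection predicts ≈11% of the 0.40 delta,
with the direct architecture offset (0.356) supplying the rest;
between-rater delta SD 0.115, which reproduces the magnitude of the
reported cohort t statistic; and a 0.25-grade difference between case
pairs whose primes differ by more than 1.5 Gleason points versus 1.5.
Case-level feature SDs (e.g. 600 px for size) make carcinomas genuinely
differ, which is what gives the matrix trials enough feature spread for
profile identification.

Two structural points mirror the design rather than a parameter:

* The two HPFs of one case display the *same* nucleus population
  (features and shapes shared; only the spatial arrangement differs).
  The study verified its paired HPFs to be morphometrically identical,
  and the property matters statistically: independently drawn
  populations would leave realized feature differences between a case's
  two fields, a common offset across raters that the across-rater paired
  t-test would read as an effect even without any selection.
* Gaze streams realize the generator's fixation targets as jittered
  50 Hz clusters joined by interpolated saccade samples, with
  consecutive targets at least `min_saccade_px` apart so that I-DT
  clusters stay separable; the detector provably recovers the generated
  sequence, and the end-to-end test asserts exactly that.

One RNG hierarchy (cohort seed → named child streams per case, rater and
trial) makes the cohort fully deterministic and lets raters be added
without perturbing existing cases.

What the generator does *not* emulate: features are drawn independently
per nucleus, whereas real size, chromasia and texture are correlated —
so a size-selecting synthetic rater shifts only fixated size, while the
human data showed concordant shifts in chromasia as well; nuclei are
star-shaped perturbed ellipses, not photorealistic chromatin; saccade
dynamics are linear interpolation; the low-power architectural prime is
represented only by the condition tag. Passing tests therefore validate
the *pipeline's statistics*, not any claim about real histology images.

## Preset regimes and problem sizes

`cohort_regime()` provides three parameterizations: `"study"` (the
default calibration above), `"pure_selection"` (no direct offset; every
rater grades through a feature rule and the tilt is scaled so selection
alone generates the full 0.40 delta — the decomposition should attribute
≈100%), and `"offset_dominated"` (selection generates 10% of the delta,
the offset 90%). The controlled regimes zero the rater-level offset
jitter so the generative split is exact; with it left in, the ratio
estimator acquires a Jensen-type upward bias from the noisy denominator.

The verification studies run at the study scale (20 × 20) for the
statistical criteria — 100 replicates for the selection-null calibration
and profile recovery, 50 seeds per regime for the decomposition bands —
using the generator's fixation targets directly. The raster/gaze layers
are exercised on a rendered 4-case × 3-rater cohort with 500 px fields
and proportionally scaled nuclei (the analysis is scale-free once slopes
are expressed per feature unit), where the file-based pipeline must agree
with an independent ground-truth recomputation to numerical tolerance
and recover the generated fixation sequences exactly.

## Known limitations

* The Crofton perimeter and the Photoshop plug-in the original
  morphometry used are different estimators; only the formula family and
  its bounds are matched, so absolute roundness values are comparable
  within this package, not across tools.
* The decomposition is a linear, univariate attribution, not a formal
  mediation analysis with interval estimates on the mediated proportion.
* With feature-free raters present, cohort summaries mix structural
  zeros with estimated fractions; the per-rater table keeps them
  distinguishable.
* The ratio `fraction_explained` is unstable when the observed delta
  approaches 0; such raters are excluded (delta exactly 0) or produce
  large fractions that the out-of-[0,1] count makes visible.
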