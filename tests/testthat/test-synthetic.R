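# Synthetic cohort generator: determinism, ground-truth consistency,
# generator/detector contract, selection calibration, grade model.

test_that("the full cohort is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_equal(a$nuclei, b$nuclei)
  expect_equal(a$fixated, b$fixated)
  expect_equal(a$grades, b$grades)
  expect_equal(a$matrix_grades, b$matrix_grades)
})

test_that("rendered fields are byte-identical under a fixed seed", {
  cfg <- small_cfg(n_cases = 1, seed = 8)
  f1 <- generate_field(cfg, 1, "tubular")
  f2 <- generate_field(cfg, 1, "tubular")
  expect_identical(f1$field$intensity, f2$field$intensity)
  expect_identical(f1$field$labels, f2$field$labels)
})

test_that("adding raters never perturbs existing cases or raters", {
  a <- simulate_cohort(small_cfg(seed = 5, n_raters = 2))
  b <- simulate_cohort(small_cfg(seed = 5, n_raters = 4,
                                 rater_features = c("size_px",
                                                    "hyperchromasia", "none",
                                                    "size_px")[1:4]))
  expect_equal(a$nuclei, b$nuclei)
  expect_equal(a$matrix_sets, b$matrix_sets)
  fx_a <- a$fixated
  fx_b <- b$fixated[b$fixated$rater_id %in% fx_a$rater_id, ]
  rownames(fx_b) <- NULL
  expect_equal(fx_a, fx_b)
})

test_that("zero boundary noise and near-unit axis ratio give round nuclei", {
  cfg <- small_cfg(n_cases = 1, nuclei_per_field = 12, boundary_noise = 0,
                   axis_ratio_range = c(1, 1.05), size_mean = 1200,
                   size_sd_within = 150, size_sd_case = 0, seed = 2)
  gf <- generate_field(cfg, 1, "tubular")
  expect_true(all(gf$nuclei$roundness >= 0.95))
  rec <- extract_nuclei(gf$field)
  expect_true(all(rec$roundness >= 0.95))
})

test_that("generated nuclei recover the configured mean size", {
  sim <- simulate_cohort(cohort_config(seed = 14))
  n <- nrow(sim$nuclei)
  expect_gte(n, 1000)
  # case-level offsets dominate the standard error of the grand mean;
  # a case's two fields display the same nuclei, so n/2 unique draws
  se <- sqrt(600^2 / 20 + 900^2 / (n / 2))
  expect_lt(abs(mean(sim$nuclei$size_px) - 3200), 3 * se)
  expect_lt(abs(mean(sim$nuclei$hyperchromasia) - 134),
            3 * sqrt(8^2 / 20 + 12^2 / (n / 2)))
})

test_that("extracted features track the generator's analytic features", {
  cfg <- small_cfg(n_cases = 1, seed = 6)
  gf <- generate_field(cfg, 1, "solid")
  rec <- extract_nuclei(gf$field)
  cmp <- merge(gf$nuclei, rec, by = "label",
               suffixes = c("_true", "_obs"))
  expect_equal(nrow(cmp), cfg$nuclei_per_field)
  expect_true(all(abs(cmp$size_px_true - cmp$size_px_obs) /
                    cmp$size_px_true < 0.03))
  expect_true(all(abs(cmp$centroid_row_true - cmp$centroid_row_obs) < 1.5))
  expect_true(all(abs(cmp$hyperchromasia_true - cmp$hyperchromasia_obs) <
                    5 * cmp$heterochromasia_true / sqrt(cmp$size_px_true)))
  expect_true(all(abs(cmp$heterochromasia_true - cmp$heterochromasia_obs) /
                    cmp$heterochromasia_true < 0.2))
  expect_true(all(abs(cmp$roundness_true - cmp$roundness_obs) < 0.06))
})

test_that("every simulated gaze stream is recovered exactly by the detector", {
  cfg <- small_cfg(seed = 11)
  sim <- simulate_cohort(cfg, gaze = "streams")
  nms <- names(sim$streams)[c(1, 5, 9, 14, 20, 24)]
  for (nm in nms) {
    st <- sim$streams[[nm]]
    j <- match(st$field_id, sim$fields$field_id)
    fld <- gazegrade:::render_field(cfg, sim$drawn[[st$field_id]],
                                    st$field_id, sim$fields$case_id[j],
                                    sim$fields$condition[j])
    fx <- assign_fixations(detect_fixations(st), fld)
    truth <- sim$fixated[sim$fixated$rater_id == st$rater_id &
                           sim$fixated$field_id == st$field_id, ]
    expect_identical(as.integer(fx$nucleus_label), as.integer(truth$label),
                     info = nm)
    expect_true(all(fx$duration_ms >= 100))
  }
})

test_that("unbiased selection leaves fixated features at the field mean", {
  # selection_strength 0: pooled fixated size within 3 SE of the pooled
  # population mean over 200 trials
  cfg <- cohort_config(n_raters = 5, selection_strength = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  fx <- merge(sim$fixated,
              sim$nuclei[, c("field_id", "label", "size_px")],
              by = c("field_id", "label"))
  expect_gte(nrow(fx), 200 * 12)
  m <- match(fx$field_id, sim$fields$field_id)
  sol <- fx$size_px[sim$fields$condition[m] == "solid"]
  tub <- fx$size_px[sim$fields$condition[m] == "tubular"]
  se <- sqrt(var(sol) / length(sol) + var(tub) / length(tub))
  expect_lt(abs(mean(sol) - mean(tub)), 3 * se)
})

test_that("strong selection shifts fixated size upward in every replicate", {
  for (s in 1:6) {
    cfg <- cohort_config(n_cases = 10, n_raters = 4,
                         rater_features = "size_px",
                         selection_strength = 0.5, seed = 800 + s)
    sim <- simulate_cohort(cfg)
    fx <- merge(sim$fixated,
                sim$nuclei[, c("field_id", "label", "size_px")],
                by = c("field_id", "label"))
    m <- match(fx$field_id, sim$fields$field_id)
    expect_gt(mean(fx$size_px[sim$fields$condition[m] == "solid"]),
              mean(fx$size_px[sim$fields$condition[m] == "tubular"]),
              label = sprintf("seed %d solid fixated size", 800 + s))
  }
})

test_that("the grade model reduces to its deterministic limits", {
  cfg <- cohort_config(quantize = TRUE)
  # noise 0, slope 0, bias 0: constant clamped rounded intercept
  g <- simulate_grades(cfg, intercept = 2.3, slope = 0,
                       feature_value = rep(0, 6),
                       condition = rep(c("tubular", "solid"), 3),
                       offset = 0, noise = rep(0, 6))
  expect_true(all(g$grade == round_half_step(2.3)))
  # noise 0, slope 0, bias 0.5: every solid latent exceeds its tubular
  # partner by exactly 0.5 before rounding
  g2 <- simulate_grades(cfg, intercept = 2, slope = 0,
                        feature_value = rep(0, 6),
                        condition = rep(c("tubular", "solid"), 3),
                        offset = 0.5, noise = rep(0, 6))
  lat <- matrix(g2$latent, nrow = 2)
  expect_true(all(lat[2, ] - lat[1, ] == 0.5))
  # grades stay on the half-step scale within [1, 3]
  set.seed(1)
  g3 <- simulate_grades(cfg, intercept = 2, slope = 0,
                        feature_value = rep(0, 500),
                        condition = "solid", offset = 0.4)
  expect_true(all(g3$grade %in% seq(1, 3, by = 0.5)))
})

test_that("half-step rounding clamps and rounds quarter ties upward", {
  expect_equal(round_half_step(c(1.24, 1.25, 1.26)), c(1, 1.5, 1.5))
  expect_equal(round_half_step(c(0.2, 3.9)), c(1, 3))
  expect_equal(round_half_step(2.75), 3)
})

test_that("cohort condition means land near the calibration targets", {
  mt <- ms <- numeric(15)
  for (s in 1:15) {
    sim <- simulate_cohort(cohort_config(seed = 2000 + s))
    ob <- observed_bias(sim$grades)
    mt[s] <- ob$condition_means["tubular"]
    ms[s] <- ob$condition_means["solid"]
  }
  expect_lt(abs(mean(mt) - 2.02), 0.1)
  expect_lt(abs(mean(ms) - 2.42), 0.1)
})

test_that("a pure architecture offset of 0.40 is recovered by the pipeline", {
  d <- numeric(15)
  for (s in 1:15) {
    sim <- simulate_cohort(cohort_config(grade_bias_delta = 0.40,
                                         selection_strength = 0,
                                         seed = 3000 + s))
    d[s] <- observed_bias(sim$grades)$mean_delta
  }
  expect_lt(abs(mean(d) - 0.40), 0.05)
})

test_that("gleason-delta strata separate by the configured effect", {
  sim <- simulate_cohort(cohort_config(seed = 77))
  st <- stratify_bias(sim$grades, by = "gleason_delta_class")
  dgt <- st$strata$mean_delta[st$strata$stratum == "gt_1_5"]
  deq <- st$strata$mean_delta[st$strata$stratum == "eq_1_5"]
  expect_gt(dgt, deq)
  expect_lt(abs((dgt - deq) - 0.25), 0.1)
})
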