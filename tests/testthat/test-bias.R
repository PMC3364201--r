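# Observed bias, stratifications, fixated-feature shifts, decomposition.

make_grades <- function(tub, sol, raters = paste0("r", seq_along(tub))) {
  do.call(rbind, lapply(seq_along(tub), function(i) {
    data.frame(rater_id = raters[i], case_id = c("c1", "c1"),
               condition = c("tubular", "solid"),
               grade = c(tub[i], sol[i]), stringsAsFactors = FALSE)
  }))
}

test_that("identical grades in both conditions give zero deltas and t = 0", {
  g <- make_grades(tub = c(2, 2.5, 1.5), sol = c(2, 2.5, 1.5))
  ob <- observed_bias(g)
  expect_true(all(ob$per_rater$observed_delta == 0))
  expect_equal(ob$t, 0)
  expect_true(ob$degenerate)
})

test_that("three-rater table reproduces the closed-form paired t", {
  g <- make_grades(tub = c(2.0, 2.1, 1.9), sol = c(2.4, 2.5, 2.2))
  ob <- observed_bias(g)
  expect_equal(ob$per_rater$observed_delta, c(0.4, 0.4, 0.3))
  expect_equal(ob$df, 2)
  expect_equal(ob$t, 11.0, tolerance = 1e-9)
  want <- oracle_paired_t(c(2.4, 2.5, 2.2), c(2.0, 2.1, 1.9))
  expect_equal(ob$t, want$t, tolerance = 1e-12)
  expect_equal(ob$p, want$p, tolerance = 1e-12)
})

test_that("paired t matches the closed-form oracle on random rater tables", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- sample(4:10, 1)
    tub <- round_half_step(rnorm(n, 2, 0.25))
    sol <- round_half_step(tub + rnorm(n, 0.4, 0.2))
    ob <- observed_bias(make_grades(tub, sol))
    want <- oracle_paired_t(sol, tub)
    expect_equal(ob$t, want$t, tolerance = 1e-10)
    expect_equal(ob$p, want$p, tolerance = 1e-10)
    expect_equal(ob$df, n - 1)
  }
})

test_that("a rater lacking one condition is reported by name", {
  g <- make_grades(tub = c(2, 2), sol = c(2.4, 2.5))
  g <- g[!(g$rater_id == "r2" & g$condition == "solid"), ]
  expect_error(observed_bias(g), "r2")
})

test_that("gleason stratification uses within-rater paired contrasts", {
  g <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(rater_id = paste0("r", i),
               case_id = rep(c("c1", "c2"), each = 2),
               condition = rep(c("tubular", "solid"), 2),
               grade = c(2, 2.2, 2, 2.7),
               gleason_delta_class = rep(c("eq_1_5", "gt_1_5"), each = 2),
               stringsAsFactors = FALSE)
  }))
  st <- stratify_bias(g, by = "gleason_delta_class")
  expect_equal(st$strata$mean_delta[st$strata$stratum == "eq_1_5"], 0.2)
  expect_equal(st$strata$mean_delta[st$strata$stratum == "gt_1_5"], 0.7)
  # constant within-rater difference: degenerate flag, no crash
  expect_true(st$test$degenerate)
  expect_equal(st$test$t, Inf)
})

test_that("experience-group ANOVA flags zero-variance deltas instead of failing", {
  g <- make_grades(tub = rep(2, 8), sol = rep(2.4, 8))
  g$rater_group <- rep(c("junior_resident", "senior_faculty"), each = 8)
  st <- stratify_bias(g, by = "rater_group")
  expect_true(st$test$degenerate)
  expect_equal(st$test$F, 0)
})

test_that("group ANOVA matches aov on a heterogeneous cohort", {
  set.seed(55)
  n <- 16
  tub <- rnorm(n, 2, 0.1); sol <- tub + rnorm(n, 0.4, 0.1)
  g <- make_grades(tub, sol)
  g$rater_group <- rep(c("junior_resident", "senior_resident",
                         "young_faculty", "senior_faculty"), each = 8)[
                           order(rep(seq_len(n), each = 2))]
  g$rater_group <- rep(rep(c("junior_resident", "senior_resident",
                             "young_faculty", "senior_faculty"), each = 4),
                       each = 2)[seq_len(nrow(g))]
  st <- stratify_bias(g, by = "rater_group")
  d <- sol - tub
  grp <- rep(c("junior_resident", "senior_resident", "young_faculty",
               "senior_faculty"), each = 4)
  ref <- anova(aov(d ~ factor(grp)))
  expect_equal(st$test$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(st$test$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(st$test$mse, ref$`Mean Sq`[2], tolerance = 1e-10)
  expect_equal(st$test$df1, 3)
  expect_equal(st$test$df2, 12)
})

test_that("ANOVA p-values are uniform under the group-null (calibration)", {
  ps <- numeric(200)
  for (s in 1:200) {
    set.seed(7000 + s)
    n <- 20
    tub <- rnorm(n, 2, 0.15); sol <- tub + rnorm(n, 0.4, 0.12)
    g <- make_grades(tub, sol)
    g$rater_group <- rep(rep(c("junior_resident", "senior_resident",
                               "young_faculty", "senior_faculty"), each = 5),
                         each = 2)[seq_len(nrow(g))]
    ps[s] <- stratify_bias(g, by = "rater_group")$test$p
  }
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical fixated features in both conditions give all t = 0", {
  ff <- do.call(rbind, lapply(c("tubular", "solid"), function(cd) {
    data.frame(rater_id = paste0("r", 1:5), condition = cd,
               size_px = 3000, hyperchromasia = 130,
               heterochromasia = 45, roundness = 0.9)
  }))
  sh <- fixation_shift(ff)
  expect_true(all(sh$t == 0))
  expect_true(all(sh$degenerate))
  expect_true(all(sh$shift == 0))
})

test_that("fixation_shift matches the paired oracle feature by feature", {
  set.seed(91)
  n <- 12
  size_tub <- rnorm(n, 3170, 100)
  grey_tub <- rnorm(n, 136, 2)
  ff <- do.call(rbind, lapply(c("tubular", "solid"), function(cd) {
    sol <- cd == "solid"
    data.frame(rater_id = sprintf("r%02d", 1:n), condition = cd,
               size_px = size_tub + if (sol) 110 + rnorm(n, 0, 40) else 0,
               hyperchromasia = grey_tub - if (sol) 4.7 + rnorm(n, 0, 1.5) else 0,
               heterochromasia = rnorm(n, 45, 0.5),
               roundness = rnorm(n, 0.88, 0.01))
  }))
  sh <- fixation_shift(ff)
  for (f in c("size_px", "hyperchromasia", "heterochromasia", "roundness")) {
    a <- ff[[f]][ff$condition == "solid"][order(ff$rater_id[ff$condition == "solid"])]
    b <- ff[[f]][ff$condition == "tubular"][order(ff$rater_id[ff$condition == "tubular"])]
    want <- oracle_paired_t(a, b)
    expect_equal(sh$t[sh$feature == f], want$t, tolerance = 1e-10)
    expect_equal(sh$p[sh$feature == f], want$p, tolerance = 1e-10)
  }
  expect_gt(sh$t[sh$feature == "size_px"], 2)
  expect_lt(sh$t[sh$feature == "hyperchromasia"], -2)
})

test_that("decomposition handles the linear-propagation and none cases", {
  selection <- data.frame(rater_id = c("r1", "r2"),
                          preferred_feature = c("size_px", NA),
                          slope = c(0.001, NA), stringsAsFactors = FALSE)
  ff <- do.call(rbind, lapply(c("tubular", "solid"), function(cd) {
    data.frame(rater_id = c("r1", "r2"), condition = cd,
               size_px = ifelse(cd == "solid", 3283, 3172),
               hyperchromasia = 130, heterochromasia = 45, roundness = 0.9)
  }))
  obs <- data.frame(rater_id = c("r1", "r2"),
                    observed_delta = c(0.111, 0.3))
  dec <- decompose_bias(selection, ff, obs)
  pr <- dec$per_rater
  # slope 0.001 x shift 111 px over observed 0.111: exactly 100%
  expect_equal(pr$predicted_delta[pr$rater_id == "r1"], 0.111)
  expect_equal(pr$fraction_explained[pr$rater_id == "r1"], 1, tolerance = 1e-12)
  # no preferred feature: predicted 0, fraction 0
  expect_equal(pr$predicted_delta[pr$rater_id == "r2"], 0)
  expect_equal(pr$fraction_explained[pr$rater_id == "r2"], 0)
  expect_equal(dec$summary$range_pct[1], 0)
})

test_that("zero observed delta excludes a rater from the summary", {
  selection <- data.frame(rater_id = c("r1", "r2"),
                          preferred_feature = c("size_px", "size_px"),
                          slope = c(0.001, 0.001), stringsAsFactors = FALSE)
  ff <- do.call(rbind, lapply(c("tubular", "solid"), function(cd) {
    data.frame(rater_id = c("r1", "r2"), condition = cd,
               size_px = ifelse(cd == "solid", 3250, 3150),
               hyperchromasia = 130, heterochromasia = 45, roundness = 0.9)
  }))
  obs <- data.frame(rater_id = c("r1", "r2"), observed_delta = c(0.25, 0))
  dec <- decompose_bias(selection, ff, obs)
  expect_true(is.na(dec$per_rater$fraction_explained[2]))
  expect_equal(dec$summary$n, 1)
  expect_equal(dec$summary$n_excluded, 1)
})

test_that("the explained fraction is invariant under affine feature rescaling", {
  mk <- function(scale, shift0) {
    list(selection = data.frame(rater_id = "r1",
                                preferred_feature = "size_px",
                                slope = 0.001 / scale,
                                stringsAsFactors = FALSE),
         ff = do.call(rbind, lapply(c("tubular", "solid"), function(cd) {
           data.frame(rater_id = "r1", condition = cd,
                      size_px = scale * ifelse(cd == "solid", 3280, 3160) + shift0,
                      hyperchromasia = 130, heterochromasia = 45,
                      roundness = 0.9)
         })))
  }
  obs <- data.frame(rater_id = "r1", observed_delta = 0.31)
  a <- mk(1, 0); b <- mk(25, 1e5)
  fa <- decompose_bias(a$selection, a$ff, obs)$per_rater$fraction_explained
  fb <- decompose_bias(b$selection, b$ff, obs)$per_rater$fraction_explained
  expect_equal(fa, fb, tolerance = 1e-12)
})

test_that("per-pair decomposition averages case-level shifts", {
  selection <- data.frame(rater_id = "r1", preferred_feature = "size_px",
                          slope = 0.001, stringsAsFactors = FALSE)
  ff <- do.call(rbind, lapply(c("c1", "c2"), function(cs) {
    do.call(rbind, lapply(c("tubular", "solid"), function(cd) {
      data.frame(rater_id = "r1", case_id = cs, condition = cd,
                 size_px = ifelse(cd == "solid", 3300, 3100) +
                   ifelse(cs == "c2", 50, -50),
                 hyperchromasia = 130, heterochromasia = 45, roundness = 0.9)
    }))
  }))
  obs <- data.frame(rater_id = "r1", observed_delta = 0.2)
  dec <- decompose_bias(selection, ff, obs, mode = "per_pair")
  expect_equal(dec$per_rater$feature_shift, 200)
  expect_equal(dec$per_rater$predicted_delta, 0.2)
  expect_equal(dec$per_rater$fraction_explained, 1)
})

test_that("the cohort summary is recomputable from the per-rater table", {
  sim <- simulate_cohort(cohort_config(n_cases = 8, n_raters = 8, seed = 17))
  dec <- analyze_cohort(sim)$decomposition
  fr <- dec$per_rater$fraction_explained
  fr <- fr[!is.na(fr)]
  expect_equal(dec$summary$mean_pct, mean(fr) * 100)
  expect_equal(dec$summary$median_pct, median(fr) * 100)
  expect_equal(dec$summary$range_pct, range(fr) * 100)
  expect_equal(dec$summary$n, length(fr))
})
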