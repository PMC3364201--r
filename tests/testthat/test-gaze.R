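# I-DT fixation detection and fixation-to-nucleus assignment.

test_that("a perfectly stable 25-sample stream yields one 500 ms fixation", {
  st <- make_stream(rep(500, 25), rep(500, 25))
  fx <- detect_fixations(st)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$duration_ms, 500)
  expect_equal(fx$x_px, 500)
  expect_equal(fx$y_px, 500)
  expect_equal(fx$n_samples, 25L)
})

test_that("five samples at 50 Hz span exactly the 100 ms minimum", {
  st <- make_stream(rep(10, 5), rep(10, 5))
  expect_equal(nrow(detect_fixations(st)), 1L)
  st4 <- make_stream(rep(10, 4), rep(10, 4))
  expect_equal(nrow(detect_fixations(st4)), 0L)
})

test_that("two 60 ms dwells separated by a large saccade yield no fixation", {
  st <- make_stream(c(rep(100, 3), rep(400, 3)), rep(100, 6))
  expect_equal(nrow(detect_fixations(st)), 0L)
})

test_that("a two-cluster stream matches the exhaustive-window oracle", {
  set.seed(5)
  x <- c(300 + rnorm(18, 0, 6), seq(320, 700, length.out = 4),
         700 + rnorm(18, 0, 6))
  y <- c(200 + rnorm(18, 0, 6), seq(200, 500, length.out = 4),
         500 + rnorm(18, 0, 6))
  st <- make_stream(x, y)
  cfg <- gaze_config()
  expect_equal(detect_fixations(st, cfg), oracle_idt(st$samples, cfg))
})

test_that("detector equals the exhaustive-window oracle on random streams", {
  cfgs <- list(gaze_config(),
               gaze_config(dispersion_px = 25),
               gaze_config(min_duration_ms = 140),
               gaze_config(dispersion_px = 60, min_duration_ms = 80))
  for (s in 1:12) {
    n <- sample(c(40, 120, 200), 1)
    st <- random_stream(n, seed = 100 + s,
                        p_jump = c(0.05, 0.15)[1 + s %% 2],
                        jitter = c(6, 12, 18)[1 + s %% 3])
    for (cfg in cfgs) {
      got <- detect_fixations(st, cfg)
      want <- oracle_idt(st$samples, cfg)
      expect_equal(got, want, info = sprintf("stream seed %d", 100 + s))
      # every reported fixation obeys the duration and dispersion rules
      if (nrow(got)) {
        expect_true(all(got$duration_ms >= cfg$min_duration_ms))
        for (k in seq_len(nrow(got))) {
          sel <- st$samples$t_ms >= got$start_ms[k] &
            st$samples$t_ms < got$start_ms[k] + got$duration_ms[k]
          disp <- diff(range(st$samples$x_px[sel])) +
            diff(range(st$samples$y_px[sel]))
          expect_lte(disp, cfg$dispersion_px)
        }
      }
    }
  }
})

test_that("shifting timestamps shifts fixation starts and nothing else", {
  st <- random_stream(150, seed = 9)
  sh <- st
  sh$samples$t_ms <- sh$samples$t_ms + 12345
  a <- detect_fixations(st)
  b <- detect_fixations(sh)
  expect_equal(b$start_ms, a$start_ms + 12345)
  expect_equal(b[, -1], a[, -1])
})

test_that("invalid samples split candidate windows", {
  x <- rep(100, 12); y <- rep(100, 12)
  st <- make_stream(x, y)
  st$samples$valid[6] <- FALSE   # splits into two 5/6-sample runs
  fx <- detect_fixations(st)
  expect_equal(nrow(fx), 2L)
  expect_true(all(fx$n_samples < 12L))
  # with only 4 valid samples on one side, that side is dropped
  st$samples$valid[5] <- FALSE
  fx2 <- detect_fixations(st)
  expect_equal(nrow(fx2), 1L)
})

test_that("assignment: inside-mask, nearest-within-radius, and unassigned", {
  f <- two_disc_field()  # nucleus 3 at (40,40) r12; nucleus 9 at (40,95) r10
  cfg <- gaze_config()
  fx <- data.frame(start_ms = 0, duration_ms = 100,
                   x_px = c(40, 5, 57, 70),  # inside 3; far bg; 5 px off 3; between
                   y_px = c(40, 5, 40, 40),
                   n_samples = 5L, nucleus_label = NA_integer_)
  got <- assign_fixations(fx, f, cfg)
  expect_identical(got$nucleus_label[1], 3L)
  expect_true(is.na(got$nucleus_label[2]))
  expect_identical(got$nucleus_label[3], 3L)   # 5 px outside mask of 3
  # each assigned centroid matches the brute-force nearest-mask scan
  for (k in seq_len(nrow(fx))) {
    expect_identical(got$nucleus_label[k],
                     oracle_nearest_label(f$labels, fx$y_px[k], fx$x_px[k],
                                          cfg$assignment_radius_px),
                     info = sprintf("fixation %d", k))
  }
})

test_that("random centroids agree with the exhaustive distance oracle", {
  f <- two_disc_field()
  cfg <- gaze_config()
  set.seed(77)
  fx <- data.frame(start_ms = 0, duration_ms = 100,
                   x_px = runif(60, 0, 119), y_px = runif(60, 0, 119),
                   n_samples = 5L, nucleus_label = NA_integer_)
  got <- assign_fixations(fx, f, cfg)
  want <- vapply(seq_len(60), function(k) {
    oracle_nearest_label(f$labels, fx$y_px[k], fx$x_px[k],
                         cfg$assignment_radius_px)
  }, integer(1))
  expect_identical(got$nucleus_label, want)
})

test_that("with zero assignment radius a fixation maps iff its pixel is labeled", {
  f <- two_disc_field()
  cfg <- gaze_config(assignment_radius_px = 1e-9)
  set.seed(3)
  fx <- data.frame(start_ms = 0, duration_ms = 100,
                   x_px = runif(80, 0, 119), y_px = runif(80, 0, 119),
                   n_samples = 5L, nucleus_label = NA_integer_)
  got <- assign_fixations(fx, f, cfg)
  for (k in seq_len(nrow(fx))) {
    lab <- f$labels[round(fx$y_px[k]) + 1, round(fx$x_px[k]) + 1]
    expect_identical(got$nucleus_label[k],
                     if (lab > 0L) lab else NA_integer_)
  }
})

test_that("fixations outside the HPF circle are never assigned", {
  f <- two_disc_field()
  f$circle <- list(center_row = 59.5, center_col = 59.5, radius = 20)
  fx <- data.frame(start_ms = 0, duration_ms = 100, x_px = 40, y_px = 40,
                   n_samples = 5L, nucleus_label = NA_integer_)
  expect_true(is.na(assign_fixations(fx, f)$nucleus_label))
  f$circle$radius <- 60
  expect_identical(assign_fixations(fx, f)$nucleus_label, 3L)
})

test_that("fixated_features deduplicates nuclei and supports dwell weighting", {
  f <- two_disc_field()
  rec <- extract_nuclei(f)
  fx1 <- data.frame(duration_ms = 200, nucleus_label = 3L)
  one <- fixated_features(fx1, rec |> transform(label = label))
  expect_equal(one$size_px, rec$size_px[rec$label == 3L])
  # two fixations on the same nucleus equal one
  fx2 <- data.frame(duration_ms = c(200, 300), nucleus_label = c(3L, 3L))
  expect_equal(fixated_features(fx2, rec), one)
  # dwell weighting: 100 ms on 3, 300 ms on 9
  fx3 <- data.frame(duration_ms = c(100, 300), nucleus_label = c(3L, 9L))
  w <- fixated_features(fx3, rec, weight = "duration")
  s3 <- rec$size_px[rec$label == 3L]; s9 <- rec$size_px[rec$label == 9L]
  expect_equal(w$size_px, (100 * s3 + 300 * s9) / 400)
  u <- fixated_features(fx3, rec)
  expect_equal(u$size_px, (s3 + s9) / 2)
  # no assigned fixations is an error with context
  fx0 <- data.frame(duration_ms = 100, nucleus_label = NA_integer_,
                    field_id = "discs")
  expect_error(fixated_features(fx0, rec), "no assigned fixations")
})

test_that("dwell table aggregates duration per nucleus", {
  fx <- data.frame(duration_ms = c(100, 300, 120),
                   nucleus_label = c(3L, 9L, 3L))
  dw <- dwell_table(fx)
  expect_equal(dw$dwell_ms[dw$nucleus_label == 3L], 220)
  expect_equal(dw$n_fixations[dw$nucleus_label == 3L], 2L)
})
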