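# End-to-end orchestration: run the full analysis over in-memory cohort
# tables or over an on-disk cohort directory, and write a synthetic cohort
# to disk in the exact dialects the analysis consumes.

#' Run the full bias analysis over cohort tables
#'
#' The statistical core of the pipeline: fixated-feature aggregation,
#' observed bias, feature-shift tests, rater profiles, and the
#' selection-explained decomposition, with the standard stratifications.
#'
#' @param nuclei per-nucleus feature table (`field_id, label` + features).
#' @param fixations assigned fixations (`rater_id, field_id,
#'   nucleus_label`, optionally `duration_ms`).
#' @param fields `field_id, case_id, condition` (+ `gleason_delta_class`).
#' @param grades HPF grade table (`rater_id, case_id, condition, grade`,
#'   optionally stratification columns).
#' @param matrix_grades matrix-trial grades (`rater_id, field_id, grade`).
#' @param matrix_features per-display mean features (`field_id` +
#'   features), e.g. from joining `matrix_sets` against `nuclei`.
#' @param rho_min,p_max profile thresholds.
#' @param weight fixated-nucleus aggregation (`"unique"` or `"duration"`).
#' @param mode decomposition mode (`"aggregate"` or `"per_pair"`).
#' @return object of class `gg_analysis`: list with `observed`,
#'   `fixated_features`, `shift`, `profiles`, `decomposition`, and
#'   `strata` (whichever stratifications the grade table supports).
#' @export
run_bias_analysis <- function(nuclei, fixations, fields, grades,
                              matrix_grades, matrix_features,
                              rho_min = 0.3, p_max = 0.05,
                              weight = "unique", mode = "aggregate") {
  validate_grades(grades)
  fixfeat <- fixated_by_rater(fixations, nuclei, fields, weight = weight,
                              per_case = (mode == "per_pair"))
  fixagg <- if (mode == "per_pair") {
    fixated_by_rater(fixations, nuclei, fields, weight = weight)
  } else fixfeat
  ob <- observed_bias(grades)
  shift <- fixation_shift(fixagg)
  prof <- profile_cohort(matrix_grades, matrix_features,
                         rho_min = rho_min, p_max = p_max)
  dec <- decompose_bias(prof$selection,
                        if (mode == "per_pair") fixfeat else fixagg,
                        ob, mode = mode)
  strata <- list()
  for (by in c("gleason_delta_class", "rater_group", "prostate_reader")) {
    if (by %in% names(grades)) strata[[by]] <- stratify_bias(grades, by)
  }
  structure(list(observed = ob, fixated_features = fixagg, shift = shift,
                 profiles = prof, decomposition = dec, strata = strata,
                 thresholds = list(rho_min = rho_min, p_max = p_max)),
            class = "gg_analysis")
}

#' @export
print.gg_analysis <- function(x, ...) {
  print(x$observed)
  cat("\nFixated-feature shifts (solid - tubular):\n")
  print(x$shift[, c("feature", "mean_tubular", "mean_solid", "shift",
                    "t", "p")], row.names = FALSE, digits = 4)
  cat("\n")
  print(x$decomposition)
  invisible(x)
}

#' Analyze a simulated cohort in memory
#'
#' Convenience wrapper running [run_bias_analysis()] on a
#' [simulate_cohort()] result, using the generator's fixation targets as
#' the assigned-fixation table (the gaze-stream route is exercised by
#' [analyze_cohort_files()]).
#'
#' @param sim a `gg_cohort`.
#' @param ... passed to [run_bias_analysis()].
#' @return a `gg_analysis`.
#' @export
analyze_cohort <- function(sim, ...) {
  stopifnot(inherits(sim, "gg_cohort"))
  fx <- sim$fixated
  names(fx)[names(fx) == "label"] <- "nucleus_label"
  run_bias_analysis(sim$nuclei, fx, sim$fields, sim$grades,
                    sim$matrix_grades, sim$matrix_features, ...)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a simulated cohort in the exact file dialects the analysis
#' consumes: per-field intensity and label rasters (TIFF), one gaze log
#' per rater and trial, the HPF grade table, matrix-trial grades and
#' nucleus sets, plus a `ground_truth/` directory (generator fixation
#' targets, rater parameters, analytic nucleus features) and a YAML
#' manifest echoing the seed and every parameter.
#'
#' @param cfg a [cohort_config()].
#' @param dir output directory (created if needed).
#' @param render write pixel rasters? (The statistical tables are always
#'   written.)
#' @return the simulated `gg_cohort`, invisibly.
#' @export
simulate_cohort_files <- function(cfg, dir, render = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gaze"), showWarnings = FALSE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  if (render) dir.create(file.path(dir, "fields"), showWarnings = FALSE)
  sim <- simulate_cohort(cfg, gaze = "streams")

  if (render) {
    for (j in seq_len(nrow(sim$fields))) {
      fid <- sim$fields$field_id[j]
      fld <- render_field(cfg, sim$drawn[[fid]], fid,
                          sim$fields$case_id[j], sim$fields$condition[j])
      write_field(fld,
                  file.path(dir, "fields", paste0(fid, "_intensity.tif")),
                  file.path(dir, "fields", paste0(fid, "_labels.tif")))
    }
  }
  for (nm in names(sim$streams)) {
    pr <- strsplit(nm, ".", fixed = TRUE)[[1]]
    write_gaze_log(sim$streams[[nm]],
                   file.path(dir, "gaze", sprintf("gaze_%s_%s.txt", pr[1], pr[2])))
  }
  write_table_gg(sim$fields, file.path(dir, "fields.csv"))
  g <- sim$grades; g$latent <- NULL
  write_table_gg(g, file.path(dir, "grades.csv"))
  write_table_gg(sim$matrix_grades, file.path(dir, "matrix_grades.csv"))
  write_table_gg(sim$matrix_sets, file.path(dir, "matrix_sets.csv"))
  write_table_gg(sim$fixated, file.path(dir, "ground_truth", "fixated.csv"))
  write_table_gg(sim$rater_params,
                 file.path(dir, "ground_truth", "rater_params.csv"))
  write_table_gg(sim$nuclei, file.path(dir, "ground_truth", "nuclei.csv"))
  write_manifest(cfg, file.path(dir, "manifest.yaml"))
  invisible(sim)
}

#' Analyze an on-disk cohort end to end
#'
#' Runs the full pipeline from files: per-field morphometry from the
#' rasters, I-DT fixation detection on every gaze log, fixation-to-nucleus
#' assignment, rater profiling and the bias decomposition. Writes the
#' output tables and a run log when `out_dir` is given.
#'
#' @param dir cohort directory as written by [simulate_cohort_files()].
#' @param gaze_cfg a [gaze_config()].
#' @param rho_min,p_max profile thresholds.
#' @param out_dir optional output directory for the result tables, report
#'   and run log.
#' @param ... passed to [run_bias_analysis()].
#' @return a `gg_analysis`, with `features` and `fixations` tables
#'   attached.
#' @export
analyze_cohort_files <- function(dir, gaze_cfg = gaze_config(),
                                 rho_min = 0.3, p_max = 0.05,
                                 out_dir = NULL, ...) {
  fields <- read_table_gg(file.path(dir, "fields.csv"))
  feats <- list(); fobjs <- list()
  for (j in seq_len(nrow(fields))) {
    fid <- fields$field_id[j]
    fld <- read_field(file.path(dir, "fields", paste0(fid, "_intensity.tif")),
                      file.path(dir, "fields", paste0(fid, "_labels.tif")),
                      field_id = fid, condition = fields$condition[j],
                      case_id = fields$case_id[j])
    D <- nrow(fld$labels)
    fld$circle <- list(center_row = (D - 1) / 2, center_col = (D - 1) / 2,
                       radius = D / 2)
    fobjs[[fid]] <- fld
    feats[[fid]] <- extract_nuclei(fld)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  logs <- list.files(file.path(dir, "gaze"), pattern = "^gaze_.*\\.txt$",
                     full.names = TRUE)
  fx <- list()
  for (lg in logs) {
    nm <- sub("^gaze_", "", sub("\\.txt$", "", basename(lg)))
    rater <- sub("_case.*$", "", nm)
    fid <- sub("^[^_]*_", "", nm)
    st <- read_gaze_log(lg, rater_id = rater, field_id = fid)
    fxs <- detect_fixations(st, gaze_cfg)
    fxs <- assign_fixations(fxs, fobjs[[fid]], gaze_cfg)
    if (nrow(fxs)) {
      fx[[length(fx) + 1L]] <- cbind(rater_id = rater, field_id = fid, fxs)
    }
  }
  fixations <- do.call(rbind, fx)

  grades <- read_table_gg(file.path(dir, "grades.csv"))
  matrix_grades <- read_table_gg(file.path(dir, "matrix_grades.csv"))
  matrix_sets <- read_table_gg(file.path(dir, "matrix_sets.csv"))
  mm <- match(paste(matrix_sets$field_id, matrix_sets$label),
              paste(features$field_id, features$label))
  if (anyNA(mm)) stop("matrix_sets refers to unknown nuclei")
  matrix_features <- do.call(rbind,
    lapply(split(mm, matrix_sets$field_id), function(ix) {
      cbind(data.frame(field_id = features$field_id[ix[1]]),
            mean_features(features[ix, , drop = FALSE]))
    }))
  rownames(matrix_features) <- NULL

  res <- run_bias_analysis(features, fixations, fields, grades,
                           matrix_grades, matrix_features,
                           rho_min = rho_min, p_max = p_max, ...)
  res$features <- features
  res$fixations <- fixations

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_gg(features, file.path(out_dir, "features.csv"))
    write_table_gg(fixations, file.path(out_dir, "fixations.csv"))
    pt <- res$profiles$selection
    write_table_gg(pt, file.path(out_dir, "rater_profiles.csv"))
    write_table_gg(res$decomposition$per_rater,
                   file.path(out_dir, "decomposition.csv"))
    write_report(res, file.path(out_dir, "report.txt"))
    mf <- tryCatch(read_manifest(file.path(dir, "manifest.yaml")),
                   error = function(e) NULL)
    write_run_log(file.path(out_dir, "run_log.txt"),
                  seed = if (is.null(mf)) NA_integer_ else mf$seed,
                  gaze_cfg = gaze_cfg, rho_min = rho_min, p_max = p_max)
  }
  res
}

#' Write the cohort summary report
#'
#' Structured-text report of the condition means, paired tests,
#' feature-shift statistics, stratifications and the decomposition
#' summary.
#'
#' @param analysis a `gg_analysis`.
#' @param path output path.
#' @export
write_report <- function(analysis, path) {
  ob <- analysis$observed
  s <- analysis$decomposition$summary
  lines <- c(
    "== Architecture-induced nuclear grading bias ==",
    sprintf("raters: %d", nrow(ob$per_rater)),
    sprintf("condition means +/- SD: tubular %.3f +/- %.3f, solid %.3f +/- %.3f",
            ob$condition_means["tubular"], ob$condition_sds["tubular"],
            ob$condition_means["solid"], ob$condition_sds["solid"]),
    sprintf("paired t(%d) = %.3f, p = %.3g", ob$df, ob$t, ob$p),
    "",
    "== Fixated-feature shifts (solid - tubular) ==")
  for (i in seq_len(nrow(analysis$shift))) {
    r <- analysis$shift[i, ]
    lines <- c(lines, sprintf(
      "%s: %.4g +/- %.3g vs %.4g +/- %.3g, shift %.4g, t(%d) = %.2f, p = %.3g",
      r$feature, r$mean_tubular, r$sd_tubular, r$mean_solid, r$sd_solid,
      r$shift, r$df, r$t, r$p))
  }
  for (by in names(analysis$strata)) {
    st <- analysis$strata[[by]]
    lines <- c(lines, "", sprintf("== Stratification by %s ==", by))
    for (i in seq_len(nrow(st$strata))) {
      r <- st$strata[i, ]
      lines <- c(lines, sprintf("%s: mean delta %.3f +/- %.3f",
                                r$stratum, r$mean_delta, r$sd_delta))
    }
    tst <- st$test
    lines <- c(lines, if (!is.null(tst$F)) {
      sprintf("one-way ANOVA: F(%d,%d) = %.3f, MSE = %.4f, p = %.3g%s",
              tst$df1, tst$df2, tst$F, tst$mse, tst$p,
              if (isTRUE(tst$degenerate)) " [degenerate]" else "")
    } else {
      sprintf("paired t(%d) = %.3f, p = %.3g%s", tst$df, tst$t, tst$p,
              if (isTRUE(tst$degenerate)) " [degenerate]" else "")
    })
  }
  lines <- c(lines, "",
    "== Selection-explained fraction of the bias ==",
    sprintf("mean %.1f%%, median %.1f%%, range %.1f%% - %.1f%% (n = %d%s)",
            s$mean_pct, s$median_pct, s$range_pct[1], s$range_pct[2], s$n,
            if (s$n_excluded) sprintf(", %d excluded", s$n_excluded) else ""),
    sprintf("fractions outside [0%%,100%%]: %d", s$n_outside_unit))
  writeLines(lines, path)
  invisible(path)
}
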