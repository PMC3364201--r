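# Readers and writers for the on-disk dialects that tie the stages
# together: rasters (TIFF/PNG), gaze logs, feature / fixation / grade /
# profile tables, the simulation manifest and the run log. All tables are
# plain delimited text with headers.

#' Read a field's intensity and label rasters
#'
#' Intensity: 8-bit grey or RGB PNG/TIFF (RGB is converted to luminance).
#' Labels: single-channel 16-bit PNG/TIFF with background 0.
#'
#' @param intensity_path,labels_path file paths (.png or .tif/.tiff).
#' @param ... passed to [labeled_field()] (`field_id`, `condition`,
#'   `case_id`, `circle`).
#' @return a [labeled_field()].
#' @export
read_field <- function(intensity_path, labels_path, ...) {
  intensity <- read_raster(intensity_path) * 255
  labels <- round(read_raster(labels_path) * 65535)
  storage.mode(labels) <- "integer"
  if (length(dim(intensity)) == 3L) intensity <- rgb_to_grey(intensity)
  labeled_field(intensity, labels, ...)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported raster format: ", path)
}

#' Write a field's rasters to disk
#'
#' Intensity as 8-bit grey TIFF, labels as 16-bit TIFF.
#'
#' @param field a [labeled_field()].
#' @param intensity_path,labels_path output paths (.tif).
#' @export
write_field <- function(field, intensity_path, labels_path) {
  tiff::writeTIFF(field$intensity / 255, intensity_path,
                  bits.per.sample = 8L)
  tiff::writeTIFF(field$labels / 65535, labels_path, bits.per.sample = 16L)
  invisible(NULL)
}

#' Read a gaze log
#'
#' Delimited text with header `t_ms,x_px,y_px,valid`, one file per rater
#' and trial (an eye-tracker open-format export). Malformed rows raise an
#' error naming the file and line number.
#'
#' @param path file path.
#' @param rater_id,field_id identifiers for the resulting stream.
#' @return a [gaze_stream()].
#' @export
read_gaze_log <- function(path, rater_id = NA_character_,
                          field_id = NA_character_) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty gaze log: ", path)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), c("t_ms", "x_px", "y_px", "valid"))) {
    stop(sprintf("%s: line 1: expected header t_ms,x_px,y_px,valid", path))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop(sprintf("%s: line %d: expected 4 fields, found %d",
                 path, bad[1] + 1L, lengths(parts)[bad[1]]))
  }
  m <- matrix(trimws(unlist(parts)), ncol = 4L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 1:3, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 3L)
  badrow <- which(apply(is.na(num), 1, any))
  if (length(badrow)) {
    stop(sprintf("%s: line %d: non-numeric value '%s'",
                 path, badrow[1] + 1L,
                 m[badrow[1], which(is.na(num[badrow[1], ]))[1]]))
  }
  valid <- m[, 4] %in% c("TRUE", "true", "1")
  gaze_stream(data.frame(t_ms = num[, 1], x_px = num[, 2], y_px = num[, 3],
                         valid = valid),
              rater_id = rater_id, field_id = field_id)
}

#' @rdname read_gaze_log
#' @param stream a [gaze_stream()] to write.
#' @export
write_gaze_log <- function(stream, path) {
  s <- stream$samples
  s$valid <- ifelse(s$valid, "1", "0")
  write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Table writers/readers for the pipeline dialects
#'
#' Thin delimited-text wrappers with the canonical column orders:
#' per-nucleus features (`field_id,label,centroid_row,centroid_col,
#' size_px,hyperchromasia,heterochromasia,roundness`), fixations
#' (`rater_id,field_id,start_ms,duration_ms,x_px,y_px,nucleus_label`),
#' grades, matrix trials, rater profiles and the per-rater decomposition.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @name table_io
#' @export
write_table_gg <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table_gg <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a grade table for pairing completeness
#'
#' Every (rater, case) must appear exactly once per architectural
#' condition; the first violating pair is named in the error.
#'
#' @param grades grade table (`rater_id, case_id, condition, grade`).
#' @return the table, invisibly, if valid.
#' @export
validate_grades <- function(grades) {
  stopifnot_cols(grades, c("rater_id", "case_id", "condition", "grade"),
                 "grades")
  key <- paste(grades$rater_id, grades$case_id)
  for (k in unique(key)) {
    cond <- grades$condition[key == k]
    for (cd in c("tubular", "solid")) {
      n <- sum(cond == cd)
      if (n != 1L) {
        pr <- strsplit(k, " ")[[1]]
        stop(sprintf(
          "grade table: rater %s, case %s has %d '%s' grades (expected 1)",
          pr[1], pr[2], n, cd))
      }
    }
  }
  invisible(grades)
}

#' Write / read the simulation manifest
#'
#' YAML echo of the seed and every generator parameter, so a simulation can
#' be reproduced or its configuration reloaded.
#'
#' @param cfg a [cohort_config()].
#' @param path manifest path (.yaml).
#' @export
write_manifest <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$slopes <- as.list(lst$slopes)
  lst$package_version <- as.character(utils::packageVersion("gazegrade"))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_manifest
#' @return `read_manifest` returns the reconstructed `cohort_config`.
#' @export
read_manifest <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$package_version <- NULL
  lst$slopes <- unlist(lst$slopes)
  args <- lst[names(lst) %in% names(formals(cohort_config))]
  do.call(cohort_config, args)
}

#' Write a run log
#'
#' Records the package version, seed, and every threshold used by an
#' analysis run.
#'
#' @param path output path.
#' @param seed integer seed of the run.
#' @param gaze_cfg a [gaze_config()].
#' @param rho_min,p_max profile thresholds.
#' @export
write_run_log <- function(path, seed, gaze_cfg = gaze_config(),
                          rho_min = 0.3, p_max = 0.05) {
  lines <- c(
    sprintf("gazegrade version: %s",
            as.character(utils::packageVersion("gazegrade"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("min_duration_ms: %g", gaze_cfg$min_duration_ms),
    sprintf("dispersion_px: %g", gaze_cfg$dispersion_px),
    sprintf("assignment_radius_px: %g", gaze_cfg$assignment_radius_px),
    sprintf("sampling_hz: %g", gaze_cfg$sampling_hz),
    sprintf("rho_min: %g", rho_min),
    sprintf("p_max: %g", p_max))
  writeLines(lines, path)
  invisible(path)
}
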