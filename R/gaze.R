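# Fixation detection (I-DT) and fixation-to-nucleus assignment.
#
# Gaze samples arrive as a 50 Hz stream of screen-pixel positions. A
# fixation is a maximal run of consecutive valid samples whose bounding-box
# dispersion (width + height) stays within a threshold and whose duration
# reaches a minimum (default 100 ms). Coordinates: x = column, y = row,
# 0-based pixel centers, matching the raster convention in morphometry.R.

#' Gaze-processing configuration
#'
#' @param min_duration_ms minimum fixation duration (default 100 ms).
#' @param dispersion_px I-DT dispersion threshold, bounding-box width +
#'   height (default 40 px, about 1 degree of visual angle at the study
#'   geometry where 0.4 degrees of tracker accuracy spans roughly 14 px).
#' @param assignment_radius_px how far outside a nucleus mask a fixation
#'   centroid may fall and still be assigned to it (default 14 px, the
#'   pixel equivalent of the 0.4-degree tracker accuracy).
#' @param sampling_hz nominal sampling rate (default 50 Hz; one sample
#'   interval 1000/sampling_hz ms).
#' @return object of class `gaze_config`.
#' @export
gaze_config <- function(min_duration_ms = 100, dispersion_px = 40,
                        assignment_radius_px = 14, sampling_hz = 50) {
  stopifnot(min_duration_ms > 0, dispersion_px > 0,
            assignment_radius_px >= 0, sampling_hz > 0)
  structure(list(min_duration_ms = min_duration_ms,
                 dispersion_px = dispersion_px,
                 assignment_radius_px = assignment_radius_px,
                 sampling_hz = sampling_hz),
            class = "gaze_config")
}

#' Construct a gaze stream
#'
#' @param samples data.frame with columns `t_ms, x_px, y_px, valid`
#'   (timestamps strictly increasing; `valid` logical).
#' @param rater_id,field_id identifiers.
#' @return object of class `gaze_stream`.
#' @export
gaze_stream <- function(samples, rater_id, field_id) {
  stopifnot_cols(samples, c("t_ms", "x_px", "y_px", "valid"), "gaze samples")
  if (is.unsorted(samples$t_ms, strictly = TRUE)) {
    stop("gaze_stream: timestamps must be strictly increasing")
  }
  structure(list(samples = samples, rater_id = rater_id, field_id = field_id),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> rater %s, field %s, %d samples (%.0f ms)\n",
              x$rater_id, x$field_id, nrow(x$samples),
              diff(range(x$samples$t_ms))))
  invisible(x)
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Scans each run of consecutive valid samples left to right. From the
#' current start sample the window is grown as long as its bounding-box
#' dispersion (width + height) stays within `dispersion_px`; if the maximal
#' window lasts at least `min_duration_ms` it is emitted as a fixation and
#' the scan resumes after it, otherwise the start advances by one sample.
#' Duration is inclusive of one trailing sample interval, so exactly five
#' samples at 50 Hz span 100 ms and pass the default threshold. Invalid
#' samples split candidate windows; no interpolation is performed.
#'
#' @param stream a [gaze_stream()] (or bare samples data.frame).
#' @param cfg a [gaze_config()].
#' @return data.frame `start_ms, duration_ms, x_px, y_px, n_samples,
#'   nucleus_label` (label NA until assigned), time-ordered and
#'   non-overlapping. Centroid is the mean of member sample positions.
#' @export
detect_fixations <- function(stream, cfg = gaze_config()) {
  s <- if (inherits(stream, "gaze_stream")) stream$samples else stream
  stopifnot_cols(s, c("t_ms", "x_px", "y_px", "valid"), "gaze samples")
  dt <- 1000 / cfg$sampling_hz
  out <- list()
  # split into runs of valid samples
  v <- as.logical(s$valid)
  runs <- split(seq_len(nrow(s)), cumsum(c(TRUE, diff(v) != 0)))
  for (run in runs) {
    if (!length(run) || !v[run[1]]) next
    t <- s$t_ms[run]; x <- s$x_px[run]; y <- s$y_px[run]
    n <- length(run)
    i <- 1L
    while (i <= n) {
      xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
      j <- i
      while (j < n) {
        nxmin <- min(xmin, x[j + 1]); nxmax <- max(xmax, x[j + 1])
        nymin <- min(ymin, y[j + 1]); nymax <- max(ymax, y[j + 1])
        if ((nxmax - nxmin) + (nymax - nymin) > cfg$dispersion_px) break
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
        j <- j + 1L
      }
      dur <- t[j] - t[i] + dt
      if (dur >= cfg$min_duration_ms) {
        out[[length(out) + 1L]] <- data.frame(
          start_ms = t[i], duration_ms = dur,
          x_px = mean(x[i:j]), y_px = mean(y[i:j]),
          n_samples = j - i + 1L, nucleus_label = NA_integer_)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start_ms = numeric(), duration_ms = numeric(),
                      x_px = numeric(), y_px = numeric(),
                      n_samples = integer(), nucleus_label = integer()))
  }
  do.call(rbind, out)
}

# nearest labeled pixel within `radius` of (row0, col0) (0-based coords);
# returns the label or NA. Ties in distance break towards the smaller label.
nearest_label <- function(labels, row0, col0, radius) {
  nr <- nrow(labels); nc <- ncol(labels)
  r1 <- max(0L, floor(row0 - radius)); r2 <- min(nr - 1L, ceiling(row0 + radius))
  c1 <- max(0L, floor(col0 - radius)); c2 <- min(nc - 1L, ceiling(col0 + radius))
  if (r1 > r2 || c1 > c2) return(NA_integer_)
  sub <- labels[(r1 + 1L):(r2 + 1L), (c1 + 1L):(c2 + 1L), drop = FALSE]
  hit <- which(sub > 0L)
  if (!length(hit)) return(NA_integer_)
  rr <- (hit - 1L) %% nrow(sub) + r1
  cc <- (hit - 1L) %/% nrow(sub) + c1
  d2 <- (rr - row0)^2 + (cc - col0)^2
  ok <- d2 <= radius^2
  if (!any(ok)) return(NA_integer_)
  lab <- as.integer(sub[hit[ok]])
  d2 <- d2[ok]
  cand <- lab[d2 == min(d2)]
  min(cand)
}

#' Assign fixations to nuclei
#'
#' A fixation whose centroid pixel carries a label is assigned that nucleus;
#' otherwise the nucleus whose mask comes nearest within
#' `assignment_radius_px`; otherwise it stays unassigned (a valid outcome).
#' If the field carries a circular-viewport annotation, fixations centred
#' outside the circle are never assigned.
#'
#' @param fixations data.frame from [detect_fixations()].
#' @param field a [labeled_field()] whose raster coordinates the fixation
#'   centroids live in (x = col, y = row, 0-based).
#' @param cfg a [gaze_config()].
#' @return `fixations` with `nucleus_label` filled in (NA = unassigned).
#' @export
assign_fixations <- function(fixations, field, cfg = gaze_config()) {
  stopifnot(inherits(field, "labeled_field"))
  labs <- field$labels
  nr <- nrow(labs); nc <- ncol(labs)
  lab_out <- rep(NA_integer_, nrow(fixations))
  for (k in seq_len(nrow(fixations))) {
    row0 <- fixations$y_px[k]; col0 <- fixations$x_px[k]
    if (!is.null(field$circle)) {
      d <- sqrt((row0 - field$circle$center_row)^2 +
                (col0 - field$circle$center_col)^2)
      if (d > field$circle$radius) next
    }
    ri <- as.integer(round(row0)) + 1L
    ci <- as.integer(round(col0)) + 1L
    if (ri >= 1L && ri <= nr && ci >= 1L && ci <= nc && labs[ri, ci] > 0L) {
      lab_out[k] <- labs[ri, ci]
    } else if (cfg$assignment_radius_px > 0) {
      lab_out[k] <- nearest_label(labs, row0, col0, cfg$assignment_radius_px)
    }
  }
  fixations$nucleus_label <- lab_out
  fixations
}

#' Mean features of the fixated nuclei
#'
#' Aggregates the morphometric features of the distinct nuclei that
#' received at least one assigned fixation. By default each nucleus counts
#' once no matter how often or long it was fixated; `weight = "duration"`
#' instead weights each nucleus by its total dwell time.
#'
#' @param fixations data.frame with `nucleus_label` (and `field_id` if
#'   `records` spans several fields) from [assign_fixations()].
#' @param records nucleus feature table from [extract_nuclei()].
#' @param weight `"unique"` (default) or `"duration"`.
#' @return one-row data.frame as from [mean_features()].
#' @export
fixated_features <- function(fixations, records,
                             weight = c("unique", "duration")) {
  weight <- match.arg(weight)
  fx <- fixations[!is.na(fixations$nucleus_label), , drop = FALSE]
  if (nrow(fx) == 0) {
    stop("fixated_features: no assigned fixations",
         if (!is.null(fixations$field_id))
           paste0(" (field ", paste(unique(fixations$field_id), collapse = ","), ")")
         else "")
  }
  keycols <- intersect(c("field_id", "nucleus_label"), names(fx))
  reckey <- if ("field_id" %in% keycols && "field_id" %in% names(records)) {
    paste(records$field_id, records$label)
  } else as.character(records$label)
  fxkey <- if ("field_id" %in% keycols && "field_id" %in% names(records)) {
    paste(fx$field_id, fx$nucleus_label)
  } else as.character(fx$nucleus_label)
  m <- match(fxkey, reckey)
  if (anyNA(m)) stop("fixated_features: fixation assigned to unknown nucleus")
  if (weight == "unique") {
    mean_features(records[unique(m), , drop = FALSE])
  } else {
    w <- tapply(fx$duration_ms, m, sum)
    rows <- as.integer(names(w))
    vals <- lapply(MORPHO_FEATURES, function(f) {
      sum(records[[f]][rows] * as.numeric(w)) / sum(w)
    })
    out <- as.data.frame(setNames(vals, MORPHO_FEATURES))
    out$n_nuclei <- length(rows)
    out
  }
}

#' Total dwell time per nucleus
#'
#' A plain tabular replacement for attention-map imagery: summed fixation
#' duration and fixation count per assigned nucleus.
#'
#' @param fixations assigned fixation table.
#' @return data.frame `nucleus_label, n_fixations, dwell_ms`.
#' @export
dwell_table <- function(fixations) {
  fx <- fixations[!is.na(fixations$nucleus_label), , drop = FALSE]
  if (!nrow(fx)) {
    return(data.frame(nucleus_label = integer(), n_fixations = integer(),
                      dwell_ms = numeric()))
  }
  agg <- aggregate(fx$duration_ms, by = list(nucleus_label = fx$nucleus_label),
                   FUN = function(d) c(n = length(d), dwell = sum(d)))
  data.frame(nucleus_label = agg$nucleus_label,
             n_fixations = as.integer(agg$x[, "n"]),
             dwell_ms = as.numeric(agg$x[, "dwell"]))
}
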