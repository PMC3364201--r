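# Architecture-induced grading bias: observed per-rater grade deltas,
# stratified comparisons, the shift in fixated-nucleus features between
# conditions, and the regression-slope decomposition of the bias into the
# fraction attributable to selective nucleus fixation.
#
# The unit of inference throughout is the rater (a cohort of 20 raters
# gives df = 19 for every paired test), matching the design in which each
# rater grades every carcinoma under both architectural conditions.

paired_t_safe <- function(a, b) {
  # paired two-tailed t across raters with a zero-variance guard:
  # identical differences give a degenerate (flagged) result, not an error
  d <- a - b
  n <- length(d)
  if (n < 2) return(list(t = NA_real_, df = n - 1, p = NA_real_, degenerate = TRUE))
  if (sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf, df = n - 1,
                p = if (mean(d) == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Observed architecture-induced grade bias
#'
#' Per-rater condition means and deltas (mean solid grade minus mean
#' tubular grade), plus the cohort-level paired two-tailed t-test across
#' raters.
#'
#' @param grades data.frame `rater_id, case_id, condition, grade` with
#'   condition in `{"tubular","solid"}`; every rater must have grades under
#'   both conditions.
#' @return list of class `observed_bias`: `per_rater` (data.frame
#'   `rater_id, mean_tubular, mean_solid, observed_delta`), `t, df, p`,
#'   `mean_delta`, `condition_means` / `condition_sds` (across raters), and
#'   a `degenerate` flag for zero-variance deltas.
#' @export
observed_bias <- function(grades) {
  stopifnot_cols(grades, c("rater_id", "case_id", "condition", "grade"),
                 "grades")
  raters <- sort(unique(grades$rater_id))
  per <- do.call(rbind, lapply(raters, function(r) {
    g <- grades[grades$rater_id == r, ]
    mt <- mean(g$grade[g$condition == "tubular"])
    ms <- mean(g$grade[g$condition == "solid"])
    if (is.nan(mt) || is.nan(ms)) {
      stop(sprintf("observed_bias: rater %s lacks one condition", r))
    }
    data.frame(rater_id = r, mean_tubular = mt, mean_solid = ms,
               observed_delta = ms - mt, stringsAsFactors = FALSE)
  }))
  tt <- paired_t_safe(per$mean_solid, per$mean_tubular)
  structure(list(
    per_rater = per,
    t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
    mean_delta = mean(per$observed_delta),
    condition_means = c(tubular = mean(per$mean_tubular),
                        solid = mean(per$mean_solid)),
    condition_sds = c(tubular = sd(per$mean_tubular),
                      solid = sd(per$mean_solid))),
    class = "observed_bias")
}

#' @export
print.observed_bias <- function(x, ...) {
  cat(sprintf(
    "Architecture-induced grade bias (%d raters)\n  tubular %.2f +/- %.2f, solid %.2f +/- %.2f\n  mean delta %.3f; paired t(%d) = %.2f, p = %.3g%s\n",
    nrow(x$per_rater), x$condition_means["tubular"], x$condition_sds["tubular"],
    x$condition_means["solid"], x$condition_sds["solid"],
    x$mean_delta, x$df, x$t, x$p,
    if (x$degenerate) " [degenerate: zero-variance deltas]" else ""))
  invisible(x)
}

#' Stratified grade bias
#'
#' Splits the per-rater bias by one of three stratifying variables:
#'
#' * `gleason_delta_class` — within-rater comparison of the delta on case
#'   pairs whose two architectural primes differed by more than 1.5 Gleason
#'   points vs at most 1.5 (paired t on the within-rater difference);
#' * `rater_group` — one-way ANOVA of per-rater deltas across experience
#'   groups;
#' * `prostate_reader` — one-way ANOVA (two groups) of per-rater deltas.
#'
#' @param grades as in [observed_bias()], additionally carrying the
#'   stratifying column.
#' @param by one of `"gleason_delta_class"`, `"rater_group"`,
#'   `"prostate_reader"`.
#' @return list: `strata` (per-stratum condition means +/- SD across raters
#'   and mean delta), `per_rater` deltas by stratum, and the test
#'   (`t, df, p` paired, or `F, df1, df2, mse, p` for ANOVA), with a
#'   `degenerate` flag where variance vanishes.
#' @export
stratify_bias <- function(grades,
                          by = c("gleason_delta_class", "rater_group",
                                 "prostate_reader")) {
  by <- match.arg(by)
  stopifnot_cols(grades, c("rater_id", "case_id", "condition", "grade", by),
                 "grades")
  strata_lvls <- sort(unique(as.character(grades[[by]])))
  raters <- sort(unique(grades$rater_id))

  if (by == "gleason_delta_class") {
    # stratum is a property of the case pair: within-rater paired contrast
    per <- do.call(rbind, lapply(raters, function(r) {
      g <- grades[grades$rater_id == r, ]
      do.call(rbind, lapply(strata_lvls, function(sl) {
        gs <- g[as.character(g[[by]]) == sl, ]
        data.frame(rater_id = r, stratum = sl,
                   mean_tubular = mean(gs$grade[gs$condition == "tubular"]),
                   mean_solid = mean(gs$grade[gs$condition == "solid"]),
                   stringsAsFactors = FALSE)
      }))
    }))
    per$delta <- per$mean_solid - per$mean_tubular
    strata <- do.call(rbind, lapply(strata_lvls, function(sl) {
      p <- per[per$stratum == sl, ]
      data.frame(stratum = sl,
                 mean_tubular = mean(p$mean_tubular), sd_tubular = sd(p$mean_tubular),
                 mean_solid = mean(p$mean_solid), sd_solid = sd(p$mean_solid),
                 mean_delta = mean(p$delta), sd_delta = sd(p$delta),
                 stringsAsFactors = FALSE)
    }))
    test <- if (length(strata_lvls) == 2) {
      a <- per$delta[per$stratum == strata_lvls[2]]
      b <- per$delta[per$stratum == strata_lvls[1]]
      paired_t_safe(a[order(per$rater_id[per$stratum == strata_lvls[2]])],
                    b[order(per$rater_id[per$stratum == strata_lvls[1]])])
    } else {
      list(t = NA_real_, df = NA, p = NA_real_, degenerate = TRUE)
    }
    return(list(by = by, strata = strata, per_rater = per, test = test))
  }

  # rater-level stratification: one delta per rater, one-way ANOVA
  ob <- observed_bias(grades)
  per <- ob$per_rater
  key <- grades[!duplicated(grades$rater_id),
                c("rater_id", by), drop = FALSE]
  per$stratum <- as.character(key[[by]][match(per$rater_id, key$rater_id)])
  strata <- do.call(rbind, lapply(sort(unique(per$stratum)), function(sl) {
    p <- per[per$stratum == sl, ]
    data.frame(stratum = sl, n = nrow(p),
               mean_delta = mean(p$observed_delta),
               sd_delta = sd(p$observed_delta), stringsAsFactors = FALSE)
  }))
  if (length(unique(per$stratum)) < 2 || var(per$observed_delta) == 0) {
    test <- list(F = if (var(per$observed_delta) == 0) 0 else NA_real_,
                 df1 = length(unique(per$stratum)) - 1,
                 df2 = nrow(per) - length(unique(per$stratum)),
                 mse = 0, p = NA_real_, degenerate = TRUE)
  } else {
    fit <- aov(observed_delta ~ factor(stratum), data = per)
    at <- anova(fit)
    test <- list(F = at$`F value`[1], df1 = at$Df[1], df2 = at$Df[2],
                 mse = at$`Mean Sq`[2], p = at$`Pr(>F)`[1],
                 degenerate = FALSE)
  }
  list(by = by, strata = strata, per_rater = per, test = test)
}

#' Shift of fixated-nucleus features between conditions
#'
#' For each morphometric feature, a paired two-tailed t-test across raters
#' of the per-rater mean feature of fixated nuclei under the solid vs the
#' tubular prime, with condition means +/- SD (across raters).
#'
#' @param fixfeat data.frame with `rater_id, condition` and the four
#'   feature columns; exactly one row per rater and condition (e.g. built
#'   by [fixated_by_rater()]).
#' @return data.frame `feature, mean_tubular, sd_tubular, mean_solid,
#'   sd_solid, shift, t, df, p, degenerate`; `shift` = solid - tubular.
#' @export
fixation_shift <- function(fixfeat) {
  stopifnot_cols(fixfeat, c("rater_id", "condition", MORPHO_FEATURES),
                 "fixated features")
  tub <- fixfeat[fixfeat$condition == "tubular", ]
  sol <- fixfeat[fixfeat$condition == "solid", ]
  tub <- tub[order(tub$rater_id), ]; sol <- sol[order(sol$rater_id), ]
  if (!identical(tub$rater_id, sol$rater_id)) {
    stop("fixation_shift: raters must have both condition rows")
  }
  do.call(rbind, lapply(MORPHO_FEATURES, function(f) {
    tt <- paired_t_safe(sol[[f]], tub[[f]])
    data.frame(feature = f,
               mean_tubular = mean(tub[[f]]), sd_tubular = sd(tub[[f]]),
               mean_solid = mean(sol[[f]]), sd_solid = sd(sol[[f]]),
               shift = mean(sol[[f]]) - mean(tub[[f]]),
               t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  }))
}

#' Per-rater fixated-feature means by condition
#'
#' Joins an assigned-fixation table against the nucleus feature table and
#' aggregates in two stages: within each field the mean feature of the
#' distinct fixated nuclei (each nucleus counted once per trial;
#' `weight = "duration"` weights by total dwell instead), then the
#' equal-weight mean of those per-field means across a rater's fields of
#' one condition. Equal field weights keep the aggregate commensurate with
#' per-trial grade averages, so that on noiseless data predicted and
#' observed grade deltas coincide exactly. With `per_case = TRUE` the
#' aggregation additionally splits by case, for the per-pair decomposition
#' mode.
#'
#' @param fixations data.frame `rater_id, field_id, nucleus_label,
#'   duration_ms` (assigned; NA labels ignored).
#' @param nuclei feature table with `field_id, label` and the four feature
#'   columns.
#' @param fields data.frame `field_id, case_id, condition` mapping fields
#'   to conditions.
#' @param weight `"unique"` or `"duration"`.
#' @param per_case also split by case?
#' @return data.frame `rater_id, condition` (+ `case_id`), four feature
#'   columns and `n_nuclei`.
#' @export
fixated_by_rater <- function(fixations, nuclei, fields,
                             weight = c("unique", "duration"),
                             per_case = FALSE) {
  weight <- match.arg(weight)
  stopifnot_cols(fixations, c("rater_id", "field_id", "nucleus_label"),
                 "fixations")
  stopifnot_cols(fields, c("field_id", "case_id", "condition"), "fields")
  fx <- fixations[!is.na(fixations$nucleus_label), , drop = FALSE]
  fx <- merge(fx, fields[, c("field_id", "case_id", "condition")],
              by = "field_id")
  m <- match(paste(fx$field_id, fx$nucleus_label),
             paste(nuclei$field_id, nuclei$label))
  if (anyNA(m)) stop("fixated_by_rater: fixation on unknown nucleus")
  fx <- cbind(fx, nuclei[m, MORPHO_FEATURES, drop = FALSE])
  grp <- if (per_case) c("rater_id", "case_id", "condition") else
    c("rater_id", "condition")
  if (weight == "unique") {
    fx <- fx[!duplicated(fx[, c("rater_id", "field_id", "nucleus_label")]), ]
    fx$.w <- 1
  } else {
    stopifnot_cols(fx, "duration_ms", "fixations")
    fx$.w <- fx$duration_ms
  }
  key <- interaction(fx[grp], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(fx, key), function(g) {
    row <- g[1, grp, drop = FALSE]
    byf <- split(g, g$field_id)
    for (f in MORPHO_FEATURES) {
      row[[f]] <- mean(vapply(byf, function(h) sum(h[[f]] * h$.w) / sum(h$.w),
                              numeric(1)))
    }
    row$n_nuclei <- nrow(g)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Decompose the grade bias into its selection-explained fraction
#'
#' For each rater, the grade shift predicted from nucleus selection alone
#' is the rater's grade-vs-feature regression slope multiplied by the shift
#' of the preferred fixated feature between conditions; the fraction
#' explained is that prediction divided by the rater's observed grade
#' delta. Raters without a qualifying preferred feature contribute a
#' predicted delta of 0 and hence fraction 0. Raters whose observed delta
#' is exactly 0 have an undefined fraction and are excluded from the
#' cohort summary (with a logged note). Fractions are reported unclipped —
#' under noise they can be negative or exceed 100% — and the summary counts
#' values outside [0, 1].
#'
#' @param selection per-rater selection table from [profile_cohort()]
#'   (`rater_id, preferred_feature, slope`).
#' @param fixfeat per-rater per-condition fixated feature means from
#'   [fixated_by_rater()] (with `case_id` when `mode = "per_pair"`).
#' @param observed an [observed_bias()] result (or its `per_rater` frame).
#' @param mode `"aggregate"` (default: one feature shift per rater from
#'   pooled fixated nuclei) or `"per_pair"` (predicted delta computed per
#'   case pair, then averaged).
#' @return object of class `bias_decomposition`: `per_rater` (data.frame
#'   `rater_id, preferred_feature, slope, feature_shift, observed_delta,
#'   predicted_delta, fraction_explained`) and `summary` (mean/median/range
#'   of fractions in percent, counts of excluded raters and of
#'   out-of-[0,1] fractions).
#' @export
decompose_bias <- function(selection, fixfeat, observed,
                           mode = c("aggregate", "per_pair")) {
  mode <- match.arg(mode)
  per_obs <- if (inherits(observed, "observed_bias")) observed$per_rater
             else observed
  stopifnot_cols(selection, c("rater_id", "preferred_feature", "slope"),
                 "selection")
  stopifnot_cols(per_obs, c("rater_id", "observed_delta"), "observed")
  if (mode == "per_pair") stopifnot_cols(fixfeat, "case_id", "fixfeat")

  rows <- lapply(seq_len(nrow(per_obs)), function(i) {
    r <- per_obs$rater_id[i]
    obs <- per_obs$observed_delta[i]
    si <- match(r, selection$rater_id)
    pref <- if (is.na(si)) NA_character_ else selection$preferred_feature[si]
    slope <- if (is.na(si)) NA_real_ else selection$slope[si]
    if (is.na(pref)) {
      shift <- 0; pred <- 0
    } else {
      ff <- fixfeat[fixfeat$rater_id == r, , drop = FALSE]
      if (mode == "aggregate") {
        shift <- mean(ff[[pref]][ff$condition == "solid"]) -
          mean(ff[[pref]][ff$condition == "tubular"])
        pred <- slope * shift
      } else {
        cases <- intersect(ff$case_id[ff$condition == "solid"],
                           ff$case_id[ff$condition == "tubular"])
        shifts <- vapply(cases, function(cs) {
          ff[[pref]][ff$condition == "solid" & ff$case_id == cs] -
            ff[[pref]][ff$condition == "tubular" & ff$case_id == cs]
        }, numeric(1))
        shift <- mean(shifts)
        pred <- slope * shift
      }
    }
    frac <- if (obs == 0) NA_real_ else pred / obs
    data.frame(rater_id = r, preferred_feature = pref,
               slope = ifelse(is.na(pref), NA_real_, slope),
               feature_shift = shift, observed_delta = obs,
               predicted_delta = pred, fraction_explained = frac,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  excl <- sum(is.na(per$fraction_explained))
  if (excl > 0) {
    gg_log(sprintf("decompose_bias: %d rater(s) with zero observed delta excluded from summary",
                   excl))
  }
  fr <- per$fraction_explained[!is.na(per$fraction_explained)]
  summ <- list(
    n = length(fr), n_excluded = excl,
    mean_pct = mean(fr) * 100, median_pct = median(fr) * 100,
    range_pct = range(fr) * 100,
    n_outside_unit = sum(fr < 0 | fr > 1))
  structure(list(per_rater = per, summary = summ, mode = mode),
            class = "bias_decomposition")
}

#' @export
print.bias_decomposition <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Selection-explained fraction of the grade bias (%d raters%s)\n  mean %.1f%%, median %.1f%%, range %.1f%%-%.1f%%\n",
    s$n, if (s$n_excluded) sprintf(", %d excluded", s$n_excluded) else "",
    s$mean_pct, s$median_pct, s$range_pct[1], s$range_pct[2]))
  if (s$n_outside_unit > 0) {
    cat(sprintf("  note: %d fraction(s) outside [0%%, 100%%]\n",
                s$n_outside_unit))
  }
  invisible(x)
}
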