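# Per-rater grading criterion: which morphometric feature drives a rater's
# nuclear grades? Estimated from the isolated-nuclei matrix trials, where
# ten nuclei cropped out of their architectural context are shown in a 2x5
# matrix and receive one grade. Each trial contributes (grade, mean feature
# vector of the 10 nuclei); Spearman correlations identify candidate
# features, the strongest passing feature is the rater's operative
# criterion, and an OLS regression of grade on that feature supplies the
# slope used later for bias attribution.

# fixed tie-break order for select_preferred()
PREFERRED_ORDER <- c("size_px", "hyperchromasia", "roundness", "heterochromasia")

#' Spearman profile of grade vs each morphometric feature
#'
#' Rank correlation (average ranks for ties, two-sided p from the
#' t-approximation) between the matrix-trial grades and each of the four
#' mean features.
#'
#' @param trials data.frame with a `grade` column and the four feature
#'   columns (`size_px, hyperchromasia, heterochromasia, roundness`); one
#'   row per matrix trial. At least 5 trials required.
#' @return data.frame `feature, rho, p` with attribute `degenerate = TRUE`
#'   when the grades are constant (all rho/p NA).
#' @export
spearman_profile <- function(trials) {
  stopifnot_cols(trials, c("grade", MORPHO_FEATURES), "matrix trials")
  if (nrow(trials) < 5) stop("spearman_profile: need at least 5 trials")
  degenerate <- length(unique(trials$grade)) < 2
  rows <- lapply(MORPHO_FEATURES, function(f) {
    x <- trials[[f]]
    if (degenerate || length(unique(x)) < 2) {
      return(data.frame(feature = f, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x, trials$grade, method = "spearman", exact = FALSE))
    data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- degenerate
  out
}

#' Select a rater's preferred morphometric feature
#'
#' A feature qualifies when |rho| exceeds `rho_min` and its p-value is below
#' `p_max` (absolute value so that darkness — lower grey level giving higher
#' grades, hence negative rho — qualifies). Among qualifying features the
#' one with the largest |rho| wins; exact ties break by the fixed order
#' size, hyperchromasia, roundness, heterochromasia. Returns
#' `NA_character_` ("none") when no feature qualifies.
#'
#' @param profile output of [spearman_profile()].
#' @param rho_min,p_max thresholds (defaults 0.3 and 0.05).
#' @return feature name or `NA_character_`.
#' @export
select_preferred <- function(profile, rho_min = 0.3, p_max = 0.05) {
  ok <- !is.na(profile$rho) & !is.na(profile$p) &
    abs(profile$rho) > rho_min & profile$p < p_max
  if (!any(ok)) return(NA_character_)
  cand <- profile[ok, , drop = FALSE]
  cand <- cand[order(-abs(cand$rho), match(cand$feature, PREFERRED_ORDER)), ]
  cand$feature[1]
}

#' Ordinary least squares of grade on one feature
#'
#' @param trials matrix-trial table as in [spearman_profile()].
#' @param feature one of the four feature names.
#' @return list `slope`, `intercept`, `feature` (grade units per feature
#'   unit). Errors on zero feature variance.
#' @export
fit_grade_regression <- function(trials, feature) {
  stopifnot(feature %in% MORPHO_FEATURES)
  if (nrow(trials) < 2) stop("fit_grade_regression: need at least 2 trials")
  x <- trials[[feature]]
  if (var(x) == 0) {
    stop(sprintf("fit_grade_regression: zero variance in %s (singular fit)",
                 feature))
  }
  fit <- lm(trials$grade ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       feature = feature, model = fit)
}

#' Full profile for one rater
#'
#' Combines [spearman_profile()], [select_preferred()] and
#' [fit_grade_regression()] into one object. Slope and intercept are NA
#' when no feature qualifies.
#'
#' @inheritParams spearman_profile
#' @inheritParams select_preferred
#' @param rater_id identifier attached to the result.
#' @return object of class `rater_profile`: list with `rater_id`,
#'   `correlations` (feature/rho/p table), `preferred_feature`, `slope`,
#'   `intercept`, `degenerate`.
#' @export
rater_profile <- function(trials, rater_id = NA_character_,
                          rho_min = 0.3, p_max = 0.05) {
  prof <- spearman_profile(trials)
  pref <- select_preferred(prof, rho_min = rho_min, p_max = p_max)
  slope <- intercept <- NA_real_
  if (!is.na(pref)) {
    fit <- fit_grade_regression(trials, pref)
    slope <- fit$slope; intercept <- fit$intercept
  }
  structure(list(rater_id = rater_id, correlations = prof,
                 preferred_feature = pref, slope = slope,
                 intercept = intercept,
                 degenerate = isTRUE(attr(prof, "degenerate"))),
            class = "rater_profile")
}

#' @export
print.rater_profile <- function(x, ...) {
  cat(sprintf("<rater_profile %s> preferred: %s", x$rater_id,
              if (is.na(x$preferred_feature)) "none" else x$preferred_feature))
  if (!is.na(x$slope)) cat(sprintf(" (slope %.3g)", x$slope))
  cat("\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Profile every rater in a cohort
#'
#' @param matrix_trials data.frame `rater_id, field_id, grade` with one row
#'   per rater and matrix display.
#' @param matrix_features data.frame `field_id` plus the four mean-feature
#'   columns of each display's 10 nuclei.
#' @inheritParams select_preferred
#' @return list with `selection` (data.frame `rater_id, preferred_feature,
#'   rho, p, slope, intercept, degenerate`) and `correlations` (long
#'   data.frame `rater_id, feature, rho, p`).
#' @export
profile_cohort <- function(matrix_trials, matrix_features,
                           rho_min = 0.3, p_max = 0.05) {
  stopifnot_cols(matrix_trials, c("rater_id", "field_id", "grade"),
                 "matrix_trials")
  stopifnot_cols(matrix_features, c("field_id", MORPHO_FEATURES),
                 "matrix_features")
  joined <- merge(matrix_trials, matrix_features, by = "field_id")
  raters <- sort(unique(joined$rater_id))
  profs <- lapply(raters, function(r) {
    rater_profile(joined[joined$rater_id == r, , drop = FALSE],
                  rater_id = r, rho_min = rho_min, p_max = p_max)
  })
  sel <- do.call(rbind, lapply(profs, function(p) {
    best <- if (is.na(p$preferred_feature)) NA_real_ else
      p$correlations$rho[p$correlations$feature == p$preferred_feature]
    bestp <- if (is.na(p$preferred_feature)) NA_real_ else
      p$correlations$p[p$correlations$feature == p$preferred_feature]
    data.frame(rater_id = p$rater_id,
               preferred_feature = p$preferred_feature,
               rho = best, p = bestp, slope = p$slope,
               intercept = p$intercept, degenerate = p$degenerate,
               stringsAsFactors = FALSE)
  }))
  corr <- do.call(rbind, lapply(profs, function(p) {
    cbind(rater_id = p$rater_id, p$correlations)
  }))
  list(selection = sel, correlations = corr, profiles = profs)
}
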