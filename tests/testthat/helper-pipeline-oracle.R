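# Independent end-to-end recomputation of the pipeline outputs from the
# same input tables, using only base loops and the closed-form statistics
# oracles (no package aggregation code). Used to verify the full analysis
# on small cohorts.

oracle_pipeline <- function(features, fixations, fields, grades,
                            matrix_grades, matrix_features,
                            rho_min = 0.3, p_max = 0.05) {
  feats <- c("size_px", "hyperchromasia", "heterochromasia", "roundness")
  raters <- sort(unique(grades$rater_id))

  # per-rater condition means and deltas
  per <- data.frame(rater_id = raters, mean_tubular = NA_real_,
                    mean_solid = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(raters)) {
    g <- grades[grades$rater_id == raters[i], ]
    per$mean_tubular[i] <- mean(g$grade[g$condition == "tubular"])
    per$mean_solid[i] <- mean(g$grade[g$condition == "solid"])
  }
  per$observed_delta <- per$mean_solid - per$mean_tubular
  tt <- oracle_paired_t(per$mean_solid, per$mean_tubular)

  # per-rater per-condition fixated feature means (distinct nuclei)
  cond_of <- setNames(fields$condition, fields$field_id)
  fixmeans <- list()
  for (r in raters) {
    fx <- fixations[fixations$rater_id == r &
                      !is.na(fixations$nucleus_label), ]
    fx <- fx[!duplicated(paste(fx$field_id, fx$nucleus_label)), ]
    for (cd in c("tubular", "solid")) {
      sel <- fx[cond_of[fx$field_id] == cd, ]
      row <- list(rater_id = r, condition = cd)
      for (f in feats) {
        # mean of per-field means over the distinct fixated nuclei
        fld_means <- vapply(unique(sel$field_id), function(fid) {
          labs <- sel$nucleus_label[sel$field_id == fid]
          mean(vapply(labs, function(lb) {
            features[[f]][features$field_id == fid & features$label == lb]
          }, numeric(1)))
        }, numeric(1))
        row[[f]] <- mean(fld_means)
      }
      fixmeans[[length(fixmeans) + 1L]] <- as.data.frame(row)
    }
  }
  fixmeans <- do.call(rbind, fixmeans)

  # profiles: spearman via rank oracle, strongest passing feature, OLS
  prof <- data.frame(rater_id = raters, preferred_feature = NA_character_,
                     slope = NA_real_, stringsAsFactors = FALSE)
  order_pref <- c("size_px", "hyperchromasia", "roundness", "heterochromasia")
  for (i in seq_along(raters)) {
    mg <- matrix_grades[matrix_grades$rater_id == raters[i], ]
    mg <- merge(mg, matrix_features, by = "field_id")
    if (length(unique(mg$grade)) < 2) next
    rho <- p <- setNames(numeric(4), feats)
    for (f in feats) {
      o <- oracle_spearman(mg[[f]], mg$grade)
      rho[f] <- o$rho; p[f] <- o$p
    }
    pass <- abs(rho) > rho_min & p < p_max
    if (!any(pass)) next
    cand <- names(rho)[pass]
    cand <- cand[order(-abs(rho[pass]), match(cand, order_pref))]
    best <- cand[1]
    prof$preferred_feature[i] <- best
    prof$slope[i] <- oracle_ols(mg[[best]], mg$grade)$slope
  }

  # decomposition
  per$predicted_delta <- 0
  per$fraction_explained <- NA_real_
  for (i in seq_along(raters)) {
    f <- prof$preferred_feature[i]
    if (!is.na(f)) {
      fm <- fixmeans[fixmeans$rater_id == raters[i], ]
      shift <- fm[[f]][fm$condition == "solid"] -
        fm[[f]][fm$condition == "tubular"]
      per$predicted_delta[i] <- prof$slope[i] * shift
    }
    if (per$observed_delta[i] != 0) {
      per$fraction_explained[i] <- per$predicted_delta[i] /
        per$observed_delta[i]
    }
  }
  fr <- per$fraction_explained[!is.na(per$fraction_explained)]
  list(per_rater = per, t = tt$t, p = tt$p, profiles = prof,
       fixmeans = fixmeans,
       summary = list(mean_pct = mean(fr) * 100,
                      median_pct = median(fr) * 100,
                      range_pct = range(fr) * 100))
}
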