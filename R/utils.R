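# Small shared helpers: half-step grade rounding, seed derivation, logging.

#' Round grades to the half-step scale
#'
#' Grades live on the 1–3 scale with intermediate half steps (1.5, 2.5)
#' explicitly allowed. Values are clamped to `[lo, hi]` and rounded to the
#' nearest 0.5; exact quarter-step ties (x.25, x.75) round half-up.
#'
#' @param x numeric vector of latent grades.
#' @param lo,hi scale bounds (defaults 1 and 3).
#' @return numeric vector on the half-step scale.
#' @export
#' @examples
#' round_half_step(c(1.24, 1.25, 2.6, 3.4))
round_half_step <- function(x, lo = 1, hi = 3) {
  x <- pmin(pmax(x, lo), hi)
  # floor(2x + 0.5) / 2 implements round-half-up on the half-step grid
  pmin(pmax(floor(2 * x + 0.5) / 2, lo), hi)
}

#' Derive a reproducible child seed
#'
#' One cohort seed fans out into independent per-case, per-rater and
#' per-trial streams via a small deterministic string hash, so that e.g.
#' adding raters to a configuration never perturbs already-generated cases.
#' Result is always a valid 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param ... path components (coerced to character) identifying the stream.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, ...) {
  parts <- as.character(unlist(list(...), use.names = FALSE))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (v in utf8ToInt(p)) h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

gg_verbose <- function() isTRUE(getOption("gazegrade.verbose", FALSE))

# debug-level log line, silenced unless options(gazegrade.verbose = TRUE)
gg_log <- function(...) {
  if (gg_verbose()) message("[gazegrade] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical feature columns; the tie-break order used by select_preferred()
# is a different, fixed order (see rater_profile.R)
MORPHO_FEATURES <- c("size_px", "hyperchromasia", "heterochromasia", "roundness")

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
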