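# Shared fixtures: small labeled fields and scaled-down cohort
# configurations used across the test files.

# uniform-grey square nucleus in an otherwise empty field
square_field <- function(side = 10, grey = 100, dim = 20, at = 6) {
  int <- matrix(grey, dim, dim)
  lab <- matrix(0L, dim, dim)
  lab[at:(at + side - 1), at:(at + side - 1)] <- 1L
  labeled_field(int, lab, field_id = "sq")
}

# two-disc field: nucleus 3 around (r1, c1), nucleus 9 around (r2, c2)
two_disc_field <- function(dim = 120, r1 = 40, c1 = 40, rad1 = 12,
                           r2 = 40, c2 = 95, rad2 = 10,
                           labels = c(3L, 9L)) {
  int <- matrix(200, dim, dim)
  lab <- matrix(0L, dim, dim)
  ii <- matrix(seq_len(dim * dim), dim, dim)
  rr <- (ii - 1) %% dim       # 0-based row
  cc <- (ii - 1) %/% dim      # 0-based col
  lab[(rr - r1)^2 + (cc - c1)^2 <= rad1^2] <- labels[1]
  int[lab == labels[1]] <- 90
  sel2 <- (rr - r2)^2 + (cc - c2)^2 <= rad2^2 & lab == 0L
  lab[sel2] <- labels[2]
  int[lab == labels[2]] <- 140
  labeled_field(int, lab, field_id = "discs")
}

# star-shaped blob with controllable radial boundary-noise amplitude
blob_mask <- function(radius = 40, amp = 0, seed = 1, modes = 3:7, pad = 6) {
  set.seed(seed)
  K <- 256
  phi <- seq(0, 2 * pi, length.out = K + 1)[-(K + 1)]
  g <- rep(0, K)
  for (m in modes) g <- g + rnorm(1) * cos(m * phi + runif(1, 0, 2 * pi))
  g <- g / sd(g)
  r <- radius * (1 + amp * g)
  s <- 2 * ceiling(max(r)) + 2 * pad + 1
  ctr <- (s + 1) / 2
  ang <- outer(seq_len(s) - ctr, seq_len(s) - ctr,
               function(i, j) atan2(i, j))
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  rin <- approx(c(phi - 2 * pi, phi, phi + 2 * pi), rep(r, 3), xout = ang)$y
  d <- outer(seq_len(s) - ctr, seq_len(s) - ctr,
             function(i, j) sqrt(i^2 + j^2))
  matrix(d <= rin, s, s)
}

# scaled-down cohort for rendered / stream-based tests: small fields and
# nuclei, slopes rescaled to the smaller feature spread
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cases = 4, n_raters = 3, nuclei_per_field = 24,
         field_diameter_px = 500, size_mean = 800, size_sd_within = 220,
         size_sd_case = 150, min_saccade_px = 100,
         slopes = c(size_px = 1.6e-3, hyperchromasia = -0.03,
                    heterochromasia = 0.06, roundness = -2),
         rater_features = c("size_px", "hyperchromasia", "none"),
         seed = 1),
    list(...))
  do.call(cohort_config, args)
}
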