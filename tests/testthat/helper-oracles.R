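# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route from the code it
# verifies: brute-force window enumeration for I-DT, contour tracing with
# corrected chain-code lengths for the perimeter, rank/closed-form
# formulas for the statistics.

# ---- shapes ------------------------------------------------------------

disc_mask <- function(r, pad = 3) {
  s <- 2 * r + 2 * pad + 1
  ctr <- (s + 1) / 2
  outer(seq_len(s), seq_len(s), function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

ellipse_mask <- function(a, b, theta = 0, pad = 3) {
  s <- 2 * ceiling(max(a, b)) + 2 * pad + 1
  ctr <- (s + 1) / 2
  outer(seq_len(s), seq_len(s), function(i, j) {
    x <- (j - ctr) * cos(theta) + (i - ctr) * sin(theta)
    y <- -(j - ctr) * sin(theta) + (i - ctr) * cos(theta)
    (x / a)^2 + (y / b)^2 <= 1
  })
}

square_mask <- function(side, pad = 3) {
  s <- side + 2 * pad
  m <- matrix(FALSE, s, s)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

# ---- perimeter oracle: Moore contour trace + corrected chain length ----

# Moore-neighbour boundary tracing (8-connectivity), returning the chain
# codes between successive boundary pixels. Assumes a single connected
# region not touching the array border.
trace_chain <- function(mask) {
  nr <- nrow(mask)
  # start: topmost, then leftmost object pixel (row-major scan)
  obj <- which(mask)
  rows <- (obj - 1L) %% nr + 1L
  cols <- (obj - 1L) %/% nr + 1L
  top <- min(rows)
  start <- c(top, min(cols[rows == top]))
  # neighbour offsets clockwise starting East: E SE S SW W NW N NE
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  inside <- function(p) mask[p[1], p[2]]
  cur <- start
  backtrack <- 5L  # came from the West (index of W), so search starts at W
  chain <- integer(0)
  path_len <- 0L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((backtrack - 1L + k) %% 8L) + 1L
      p <- c(cur[1] + dr[d], cur[2] + dc[d])
      if (inside(p)) {
        chain <- c(chain, d)
        # new backtrack: direction pointing back to previous pixel, +1 cw
        backtrack <- ((d + 4L - 1L + 1L) %% 8L) + 1L
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) return(integer(0))  # isolated pixel
    path_len <- path_len + 1L
    if (all(cur == start) || path_len > 8L * length(obj)) break
  }
  chain
}

# corrected chain-code length (Vossepoel & Smeulders):
# L = 0.980 * N_even + 1.406 * N_odd - 0.091 * N_corner
chain_perimeter <- function(mask) {
  ch <- trace_chain(mask)
  if (!length(ch)) return(4)  # single pixel: unit-square boundary
  diag_step <- ch %% 2L == 0L  # even index = diagonal (SE, SW, NW, NE)
  ne <- sum(!diag_step)
  no <- sum(diag_step)
  nc <- sum(ch != c(ch[-1], ch[1]))
  0.980 * ne + 1.406 * no - 0.091 * nc
}

oracle_form_factor <- function(mask) {
  min(4 * pi * sum(mask) / chain_perimeter(mask)^2, 1)
}

# ---- I-DT oracle: exhaustive window enumeration ------------------------

# For every candidate start, recompute the dispersion of every candidate
# window from scratch; emit the maximal admissible window when it meets
# the duration rule, exactly as the greedy scan should.
oracle_idt <- function(samples, cfg) {
  dt <- 1000 / cfg$sampling_hz
  out <- list()
  v <- as.logical(samples$valid)
  runs <- split(seq_len(nrow(samples)), cumsum(c(TRUE, diff(v) != 0)))
  for (run in runs) {
    if (!length(run) || !v[run[1]]) next
    t <- samples$t_ms[run]; x <- samples$x_px[run]; y <- samples$y_px[run]
    n <- length(run)
    i <- 1L
    while (i <= n) {
      jmax <- i
      for (j in i:n) {
        disp <- diff(range(x[i:j])) + diff(range(y[i:j]))
        if (disp > cfg$dispersion_px) break
        jmax <- j
      }
      dur <- t[jmax] - t[i] + dt
      if (dur >= cfg$min_duration_ms) {
        out[[length(out) + 1L]] <- data.frame(
          start_ms = t[i], duration_ms = dur,
          x_px = mean(x[i:jmax]), y_px = mean(y[i:jmax]),
          n_samples = jmax - i + 1L, nucleus_label = NA_integer_)
        i <- jmax + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start_ms = numeric(), duration_ms = numeric(),
                      x_px = numeric(), y_px = numeric(),
                      n_samples = integer(), nucleus_label = integer()))
  }
  do.call(rbind, out)
}

# ---- assignment oracle: full-raster nearest labeled pixel --------------

oracle_nearest_label <- function(labels, row0, col0, radius) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(NA_integer_)
  nr <- nrow(labels)
  rr <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  d2 <- (rr - row0)^2 + (cc - col0)^2
  ok <- d2 <= radius^2
  if (!any(ok)) return(NA_integer_)
  lab <- as.integer(labels[idx[ok]]); d2 <- d2[ok]
  min(lab[d2 == min(d2)])
}

# ---- statistics oracles ------------------------------------------------

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), n - 2))
}

oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1))
}

oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# ---- stream construction helpers ---------------------------------------

make_stream <- function(x, y, dt = 20, t0 = 0, valid = TRUE,
                        rater = "r1", field = "f1") {
  n <- length(x)
  gaze_stream(data.frame(t_ms = t0 + (seq_len(n) - 1) * dt,
                         x_px = x, y_px = y,
                         valid = rep(valid, length.out = n)),
              rater_id = rater, field_id = field)
}

random_stream <- function(n, seed, p_jump = 0.1, jump = 300, jitter = 8) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  cx <- runif(1, 100, 900); cy <- runif(1, 100, 900)
  for (i in seq_len(n)) {
    if (runif(1) < p_jump) { cx <- runif(1, 100, 900); cy <- runif(1, 100, 900) }
    x[i] <- cx + rnorm(1, 0, jitter)
    y[i] <- cy + rnorm(1, 0, jitter)
  }
  make_stream(x, y)
}
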