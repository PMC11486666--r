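# Fixture builders shared across test files. Everything is generated in
# code; no fixture files.

# A track table from explicit frames and positions (matrix n x 3).
make_track <- function(frames, pos, id = "t1", dt = 0.5, ...) {
  pos <- matrix(pos, ncol = 3)
  df <- data.frame(track_id = id, frame = as.integer(frames),
                   x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3], ...)
  as_track_tbl(df, acquisition = acquisition_spec(frame_interval = dt))
}

# Straight-line mover: speed um/min along +x, n_frames observations.
make_ballistic <- function(speed, n_frames, id = "b1", dt = 0.5) {
  f <- 0:(n_frames - 1)
  make_track(f, cbind(speed * f * dt, 0, 0), id = id, dt = dt)
}

# A track whose consecutive steps have the given lengths (um), along +x.
make_step_track <- function(step_lengths, id = "s1", dt = 0.5) {
  x <- c(0, cumsum(step_lengths))
  make_track(seq_along(x) - 1L, cbind(x, 0, 0), id = id, dt = dt)
}

# Independent slot-by-slot recomputation of centered-difference velocities
# (deliberately naive; the oracle for centered_velocities()).
brute_centered <- function(df, dt) {
  f0 <- min(df$frame); f1 <- max(df$frame)
  res <- NULL
  for (fr in f0:f1) {
    rows <- lapply(c(fr - 1, fr, fr + 1), function(ff) {
      i <- which(df$frame == ff)
      if (length(i) == 1) as.numeric(df[i, c("x_um", "y_um", "z_um")]) else NULL
    })
    if (!any(vapply(rows, is.null, logical(1)))) {
      u <- (rows[[3]] - rows[[1]]) / (2 * dt)
      res <- rbind(res, c(fr, u))
    }
  }
  res
}

# Random track with gaps, uniform positions; returns the track table.
random_gapped_track <- function(n = 50, drop = 0.2, id = "r1", dt = 0.5) {
  frames <- 0:(n - 1)
  keep <- c(TRUE, runif(n - 2) > drop, TRUE)
  make_track(frames[keep], matrix(runif(3 * sum(keep), -50, 50), ncol = 3),
             id = id, dt = dt)
}

# Gaussian blob of per-cell (q_bar, a_bar) summaries.
qa_blob <- function(n, q, a, sd_q = 0.03, sd_a = 0.1, prefix = "c") {
  tibble::tibble(track_id = paste0(prefix, seq_len(n)),
                 q_bar = rnorm(n, q, sd_q),
                 a_bar = pmax(rnorm(n, a, sd_a), 1e-3))
}

# Three-population (q_bar, a_bar) mixture with known proportions, matching
# the high / medium / low motility geometry.
qa_mixture <- function(n = 300, props = c(0.5, 0.3, 0.2)) {
  counts <- round(props * n)
  counts[1] <- n - sum(counts[-1])
  dplyr::bind_rows(
    qa_blob(counts[1], q = 0.80, a = 4.0, prefix = "hi"),
    qa_blob(counts[2], q = 0.80, a = 1.0, prefix = "md"),
    qa_blob(counts[3], q = 0.15, a = 1.0, prefix = "lo")
  )
}

# Brute-force single-step Bayes update over the full grid: normalized
# elementwise product of a (possibly uniform) prior and the pointwise
# likelihood formula, computed with scalar loops.
brute_posterior <- function(u_prev, u_curr, grid, prior = NULL) {
  nq <- length(grid$q); na <- length(grid$a)
  if (is.null(prior)) prior <- matrix(1 / (nq * na), nq, na)
  post <- matrix(0, nq, na)
  for (i in seq_len(nq)) {
    for (j in seq_len(na)) {
      a <- grid$a[j]
      r <- sum((u_curr - grid$q[i] * u_prev)^2)
      post[i, j] <- prior[i, j] * (2 * pi * a^2)^(-3 / 2) * exp(-r / (2 * a^2))
    }
  }
  post / sum(post)
}

# Constructed cohort with known durations, displacements and valid-velocity
# counts (dt = 0.5 min):
#   long_fast : 21 frames = 10 min, 3 um/min ballistic, net 30 um, 19 valid
#   short     :  8 frames = 3.5 min, 3 um/min, fails every duration floor
#   slow      : 21 frames = 10 min, 1 um/min, net 10 um (< 15 um)
#   gappy     : frames 0..19 minus every third -> 9.5 min, no triple of
#               consecutive observations, 0 valid velocities, net 28.5 um
#   mid       : 10 frames = 4.5 min, 4 um/min, net 18 um, 8 valid
#   fourteen  : 16 frames = 7.5 min, 3 um/min, exactly 14 valid velocities
make_filter_cohort <- function() {
  gap_frames <- setdiff(0:19, seq(2, 19, by = 3))
  as_track_tbl(dplyr::bind_rows(
    tibble::as_tibble(make_ballistic(3, 21, id = "long_fast")),
    tibble::as_tibble(make_ballistic(3, 8, id = "short")),
    tibble::as_tibble(make_ballistic(1, 21, id = "slow")),
    tibble::as_tibble(make_track(gap_frames,
                                 cbind(gap_frames * 1.5, 0, 0), id = "gappy")),
    tibble::as_tibble(make_ballistic(4, 10, id = "mid")),
    tibble::as_tibble(make_ballistic(3, 16, id = "fourteen"))
  ))
}

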