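#' Per-step parameter path for the heterogeneous random walk
#'
#' The velocity model is a first-order autoregressive process
#' `u_t = q_t * u_{t-1} + a_t * n_t` with standard 3D Gaussian noise `n_t`.
#' A parameter path fixes the persistence `q_t` (in \[-1, 1\]) and activity
#' `a_t` (µm/min, >= 0) at every step, making the walk heterogeneous.
#'
#' @param n_steps Number of steps (>= 1).
#' @param q,a Starting persistence and activity.
#' @param regime `"constant"` (values held fixed), `"step"` (switch to
#'   `q_final`/`a_final` after `change_at` steps), or `"smooth"` (linear
#'   interpolation from start to final over the whole path).
#' @param q_final,a_final End values for `"step"`/`"smooth"` regimes.
#' @param change_at For `"step"`: the number of initial steps holding the
#'   starting values; steps `change_at + 1 .. n_steps` use the final values.
#'
#' @return A tibble with columns `step`, `q`, `a` and the regime recorded in
#'   the `regime` attribute.
#' @examples
#' parameter_path(10, q = 0.6, a = 2)
#' parameter_path(10, q = 0.8, a = 2, regime = "step", q_final = 0.2,
#'                change_at = 5)
#' @export
parameter_path <- function(n_steps, q, a,
                           regime = c("constant", "step", "smooth"),
                           q_final = q, a_final = a, change_at = NULL) {
  regime <- match.arg(regime)
  if (n_steps < 1) abort("`n_steps` must be >= 1")
  qs <- switch(regime,
    constant = rep(q, n_steps),
    step = {
      if (is.null(change_at)) abort("`change_at` is required for the step regime")
      c(rep(q, change_at), rep(q_final, n_steps - change_at))
    },
    smooth = seq(q, q_final, length.out = n_steps)
  )
  as_ <- switch(regime,
    constant = rep(a, n_steps),
    step = c(rep(a, change_at), rep(a_final, n_steps - change_at)),
    smooth = seq(a, a_final, length.out = n_steps)
  )
  if (any(qs < -1 | qs > 1)) abort("persistence q must lie in [-1, 1]")
  if (any(as_ < 0)) abort("activity a must be >= 0")
  structure(tibble(step = seq_len(n_steps), q = qs, a = as_),
            regime = regime)
}

#' Simulate one track from a parameter path
#'
#' Draws velocities by the AR(1) recursion `u_t = q_t u_{t-1} + a_t n_t`
#' and integrates positions forward from the origin,
#' `x_t = x_{t-1} + u_t * dt`. The generating ("true") velocity of each step
#' is attached as extra columns, so inference can be validated against
#' ground truth.
#'
#' @param path A [parameter_path()].
#' @param acquisition An [acquisition_spec()].
#' @param initial_speed_mode `"stationary"` draws each component of the
#'   initial velocity from `Normal(0, a_1^2 / (1 - q_1^2))` when `|q_1| < 1`
#'   (zero otherwise), so short tracks carry no start-up transient; `"zero"`
#'   starts at rest (useful for closed-form checks).
#' @param origin Numeric length-3 start position (µm).
#' @param track_id Identifier for the generated track.
#' @param initial_velocity Optional explicit initial velocity (length 3),
#'   overriding `initial_speed_mode`.
#'
#' @return A `track_tbl` with one track: frames `0..n_steps`, positions, and
#'   true velocity columns `ux_true_um_min`, `uy_true_um_min`,
#'   `uz_true_um_min` (the velocity that moved the cell into each frame;
#'   `NA` at frame 0).
#' @details Uses the current RNG state; seed at the cohort level (see
#'   [simulate_cohort()]) for reproducibility.
#' @examples
#' p <- parameter_path(20, q = 0.6, a = 2)
#' tr <- simulate_track(p)
#' @export
simulate_track <- function(path, acquisition = acquisition_spec(),
                           initial_speed_mode = c("stationary", "zero"),
                           origin = c(0, 0, 0), track_id = "cell_1",
                           initial_velocity = NULL) {
  initial_speed_mode <- match.arg(initial_speed_mode)
  stopifnot(is.data.frame(path), all(c("q", "a") %in% names(path)))
  n <- nrow(path)
  dt <- acquisition$frame_interval
  q <- path$q; a <- path$a
  if (!is.null(initial_velocity)) {
    u0 <- as.numeric(initial_velocity)
    stopifnot(length(u0) == 3L)
  } else if (initial_speed_mode == "stationary" && abs(q[1]) < 1) {
    u0 <- rnorm(3, 0, a[1] / sqrt(1 - q[1]^2))
  } else {
    u0 <- c(0, 0, 0)
  }
  u <- matrix(0, n, 3L)
  noise <- matrix(rnorm(3L * n), n, 3L)
  prev <- u0
  for (t in seq_len(n)) {
    prev <- q[t] * prev + a[t] * noise[t, ]
    u[t, ] <- prev
  }
  x <- apply(u * dt, 2L, cumsum)
  if (n == 1L) x <- matrix(x, 1L)
  pos <- rbind(origin, sweep(x, 2L, origin, "+"))
  dimnames(pos) <- NULL
  df <- tibble(
    track_id = track_id,
    frame = 0:n,
    x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
    ux_true_um_min = c(NA_real_, u[, 1]),
    uy_true_um_min = c(NA_real_, u[, 2]),
    uz_true_um_min = c(NA_real_, u[, 3])
  )
  as_track_tbl(df, acquisition = acquisition)
}

#' Describe one sub-population of a simulated cohort
#'
#' @param label Sub-population name (becomes the `population` condition
#'   label on generated tracks).
#' @param fraction Proportion of cells in the cohort, in \[0, 1\].
#' @param q,a Constant persistence and activity of the population.
#' @param n_steps Track length in steps.
#' @param immobile If `TRUE` the population models dead cells: `q` and `a`
#'   are forced to 0 and tracks do not move.
#' @return A one-row tibble.
#' @export
population_spec <- function(label, fraction, q, a, n_steps, immobile = FALSE) {
  if (immobile) { q <- 0; a <- 0 }
  if (q < -1 || q > 1) abort("persistence q must lie in [-1, 1]")
  if (a < 0) abort("activity a must be >= 0")
  tibble(label = as.character(label), fraction = fraction, q = q, a = a,
         n_steps = as.integer(n_steps), immobile = immobile)
}

#' Default three-mode mixture plus a dead-cell fraction
#'
#' A cohort emulating the sub-population structure seen in motile T cell
#' populations: a fast persistent mode, a slow persistent mode, a slow
#' erratic mode, and a fraction of immobile (dead) cells that downstream
#' filters are expected to remove. Track lengths span 10-25 min at 30 s
#' frames.
#'
#' @return A tibble of [population_spec()] rows.
#' @export
motility_mixture <- function() {
  bind_rows(
    population_spec("hi_a_hi_q", 0.40, q = 0.7, a = 2.0, n_steps = 50),
    population_spec("lo_a_hi_q", 0.25, q = 0.7, a = 1.0, n_steps = 40),
    population_spec("lo_a_lo_q", 0.25, q = 0.2, a = 0.6, n_steps = 30),
    population_spec("dead", 0.10, q = 0, a = 0, n_steps = 20, immobile = TRUE)
  )
}

#' Cohort simulation settings
#'
#' @param populations Tibble of [population_spec()] rows; fractions must sum
#'   to 1 (within 1e-9).
#' @param n_cells Total number of cells (>= 1).
#' @param frame_interval Frame interval in minutes.
#' @param gap_rate Per-slot probability that an interior observation is
#'   missing (0 <= rate < 1).
#' @param seed Integer seed; identical configs give identical cohorts.
#' @param initial_speed_mode Passed to [simulate_track()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(populations = motility_mixture(), n_cells = 100L,
                              frame_interval = 0.5, gap_rate = 0, seed = 1L,
                              initial_speed_mode = "stationary") {
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  if (gap_rate < 0 || gap_rate >= 1) abort("`gap_rate` must be in [0, 1)")
  if (abs(sum(populations$fraction) - 1) > 1e-9) {
    abort("population fractions must sum to 1")
  }
  structure(list(populations = populations, n_cells = as.integer(n_cells),
                 frame_interval = frame_interval, gap_rate = gap_rate,
                 seed = as.integer(seed),
                 initial_speed_mode = initial_speed_mode),
            class = "simulation_config")
}

# Largest-remainder allocation of n items to fractions.
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a cohort of tracks with ground truth
#'
#' Allocates cells to sub-populations by largest-remainder rounding of the
#' fractions, simulates each track from its population's constant parameter
#' path, optionally knocks out interior observations at `gap_rate`, and
#' returns both the track table and a per-step ground-truth table.
#'
#' @param config A [simulation_config()].
#' @return A list with `tracks` (a `track_tbl`; condition column
#'   `population`) and `truth` (tibble `track_id, population, step, q_true,
#'   a_true`).
#' @examples
#' cfg <- simulation_config(n_cells = 20, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$tracks$population[!duplicated(cohort$tracks$track_id)])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  acq <- acquisition_spec(frame_interval = config$frame_interval)
  pops <- config$populations
  counts <- allocate_counts(pops$fraction, config$n_cells)
  withr::with_seed(config$seed, {
    tracks <- vector("list", config$n_cells)
    truth <- vector("list", config$n_cells)
    cell <- 0L
    for (p in seq_len(nrow(pops))) {
      for (i in seq_len(counts[p])) {
        cell <- cell + 1L
        id <- sprintf("cell_%04d", cell)
        pp <- parameter_path(pops$n_steps[p], q = pops$q[p], a = pops$a[p])
        tr <- simulate_track(pp, acquisition = acq,
                             initial_speed_mode = config$initial_speed_mode,
                             track_id = id)
        tr$population <- pops$label[p]
        if (config$gap_rate > 0) {
          tr <- inject_gaps(tr, config$gap_rate)
        }
        tracks[[cell]] <- as_tibble(tr)
        truth[[cell]] <- tibble(track_id = id, population = pops$label[p],
                                step = pp$step, q_true = pp$q, a_true = pp$a)
      }
    }
    list(
      tracks = as_track_tbl(bind_rows(tracks), acquisition = acq,
                            provenance = paste0("simulate_cohort seed=", config$seed)),
      truth = bind_rows(truth)
    )
  })
}

#' Remove interior observations of a track at random
#'
#' Each interior slot is dropped independently with probability `gap_rate`;
#' the first and last observations are never removed, so the track's span
#' and duration are preserved. Gaps matter downstream: a missing frame
#' invalidates the centered-difference velocities on both sides.
#'
#' @param tracks A track table (one or several tracks).
#' @param gap_rate Probability in \[0, 1).
#' @return The track table with rows removed. Uses the current RNG state.
#' @export
inject_gaps <- function(tracks, gap_rate) {
  if (gap_rate < 0 || gap_rate >= 1) abort("`gap_rate` must be in [0, 1)")
  if (gap_rate == 0 || nrow(tracks) == 0) return(tracks)
  acq <- get_acquisition(tracks)
  keep <- unlist(lapply(.split_tracks(tracks), function(df) {
    n <- nrow(df)
    k <- rep(TRUE, n)
    if (n > 2) k[2:(n - 1)] <- runif(n - 2) >= gap_rate
    k
  }), use.names = FALSE)
  as_track_tbl(as_tibble(tracks)[keep, , drop = FALSE], acquisition = acq,
               provenance = attr(tracks, "provenance"))
}
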