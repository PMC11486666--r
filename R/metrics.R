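# Shared velocity-series schema: one row per grid slot inside each track's
# span, with `observed` (position present) and `valid` (velocity estimate
# defined at that slot). Invalid slots carry NA velocities.
.empty_velocity_tbl <- function() {
  tibble(track_id = character(), frame = integer(), observed = logical(),
         valid = logical(), ux_um_min = numeric(), uy_um_min = numeric(),
         uz_um_min = numeric())
}

.velocity_tbl <- function(track_id, frames, observed, valid, u) {
  tibble(track_id = track_id, frame = frames, observed = observed,
         valid = valid,
         ux_um_min = ifelse(valid, u[, 1], NA_real_),
         uy_um_min = ifelse(valid, u[, 2], NA_real_),
         uz_um_min = ifelse(valid, u[, 3], NA_real_))
}

#' Centered-difference velocity series
#'
#' Estimates the velocity at slot t by the second-order centered finite
#' difference `u_t = (x_{t+1} - x_{t-1}) / (2 dt)`. A slot is valid only when
#' slots t-1, t and t+1 are all observed: endpoints never yield a velocity
#' and any gap invalidates the estimates on both sides of it.
#'
#' @param tracks A track table.
#' @param acquisition Optional [acquisition_spec()] override.
#' @return A tibble with one row per grid slot per track: `track_id`,
#'   `frame`, `observed`, `valid`, `ux_um_min`, `uy_um_min`, `uz_um_min`.
#' @seealso [forward_velocities()] for the one-step difference used when
#'   validating against simulated ground truth.
#' @export
centered_velocities <- function(tracks, acquisition = NULL) {
  if (nrow(tracks) == 0) return(.empty_velocity_tbl())
  acq <- get_acquisition(tracks, acquisition)
  dt <- acq$frame_interval
  out <- lapply(.split_tracks(tracks), function(df) {
    g <- .track_grid(df)
    n <- length(g$frames)
    u <- matrix(NA_real_, n, 3L)
    valid <- rep(FALSE, n)
    if (n >= 3) {
      mid <- 2:(n - 1)
      valid[mid] <- g$observed[mid - 1] & g$observed[mid] & g$observed[mid + 1]
      u[mid, ] <- (g$pos[mid + 1, , drop = FALSE] -
                     g$pos[mid - 1, , drop = FALSE]) / (2 * dt)
    }
    .velocity_tbl(df$track_id[1], g$frames, g$observed, valid, u)
  })
  bind_rows(out)
}

#' One-step (forward-difference) velocity series
#'
#' Estimates the velocity that moved the cell into slot t,
#' `u_t = (x_t - x_{t-1}) / dt`, valid when both slots are observed. For
#' tracks integrated by the simulator this recovers the generating AR(1)
#' velocities exactly, which makes it the estimator of choice when checking
#' parameter recovery against ground truth; centered differences remain the
#' standard for sampled microscope data.
#'
#' @inheritParams centered_velocities
#' @return Same schema as [centered_velocities()].
#' @export
forward_velocities <- function(tracks, acquisition = NULL) {
  if (nrow(tracks) == 0) return(.empty_velocity_tbl())
  acq <- get_acquisition(tracks, acquisition)
  dt <- acq$frame_interval
  out <- lapply(.split_tracks(tracks), function(df) {
    g <- .track_grid(df)
    n <- length(g$frames)
    u <- matrix(NA_real_, n, 3L)
    valid <- rep(FALSE, n)
    if (n >= 2) {
      cur <- 2:n
      valid[cur] <- g$observed[cur - 1] & g$observed[cur]
      u[cur, ] <- (g$pos[cur, , drop = FALSE] -
                     g$pos[cur - 1, , drop = FALSE]) / dt
    }
    .velocity_tbl(df$track_id[1], g$frames, g$observed, valid, u)
  })
  bind_rows(out)
}

#' Frame-to-frame instantaneous speeds
#'
#' The speed over each pair of consecutive observed frames,
#' `||x_{t+1} - x_t|| / dt`, keyed by the first frame of the pair. Pairs
#' spanning a gap are skipped. This is the conventional tracking-software
#' speed estimate underlying the mean track speed and the arrest
#' coefficient.
#'
#' @inheritParams centered_velocities
#' @return A tibble `track_id`, `frame`, `speed_um_min`.
#' @export
frame_speeds <- function(tracks, acquisition = NULL) {
  if (nrow(tracks) == 0) {
    return(tibble(track_id = character(), frame = integer(),
                  speed_um_min = numeric()))
  }
  acq <- get_acquisition(tracks, acquisition)
  dt <- acq$frame_interval
  out <- lapply(.split_tracks(tracks), function(df) {
    n <- nrow(df)
    if (n < 2) {
      return(tibble(track_id = character(), frame = integer(),
                    speed_um_min = numeric()))
    }
    consec <- diff(df$frame) == 1L
    if (!any(consec)) {
      return(tibble(track_id = character(), frame = integer(),
                    speed_um_min = numeric()))
    }
    pos <- as.matrix(df[, c("x_um", "y_um", "z_um")])
    d <- sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
    tibble(track_id = df$track_id[1], frame = df$frame[-n][consec],
           speed_um_min = d[consec] / dt)
  })
  bind_rows(out)
}

#' Mean track speed per cell
#'
#' Arithmetic mean of the frame-to-frame speeds of each track. Tracks with
#' no valid speed (fewer than two consecutive observations) are reported
#' with `NA`, and are excluded from cohort summaries rather than treated as
#' zero.
#'
#' @inheritParams centered_velocities
#' @return A tibble `track_id`, `mean_speed_um_min`, `n_speeds`.
#' @export
mean_track_speed <- function(tracks, acquisition = NULL) {
  sp <- frame_speeds(tracks, acquisition)
  ids <- unique(tracks$track_id)
  agg <- sp %>%
    group_by(.data$track_id) %>%
    summarise(mean_speed_um_min = mean(.data$speed_um_min),
              n_speeds = dplyr::n(), .groups = "drop")
  out <- left_join(tibble(track_id = ids), agg, by = "track_id")
  out$n_speeds[is.na(out$n_speeds)] <- 0L
  out
}

#' Arrest coefficient per cell
#'
#' Percentage of a track's frame-to-frame speeds strictly below the arrest
#' threshold (default 2 µm/min); a speed exactly at the threshold does not
#' count as arrested.
#'
#' @inheritParams centered_velocities
#' @param threshold Arrest threshold in µm/min.
#' @return A tibble `track_id`, `arrest_pct`, `n_speeds`.
#' @export
arrest_coefficient <- function(tracks, threshold = 2, acquisition = NULL) {
  sp <- frame_speeds(tracks, acquisition)
  ids <- unique(tracks$track_id)
  agg <- sp %>%
    group_by(.data$track_id) %>%
    summarise(arrest_pct = 100 * mean(.data$speed_um_min < threshold),
              n_speeds = dplyr::n(), .groups = "drop")
  out <- left_join(tibble(track_id = ids), agg, by = "track_id")
  out$n_speeds[is.na(out$n_speeds)] <- 0L
  out
}

#' Turning angles between successive displacement steps
#'
#' Angle (degrees, in \[0, 180\]) between successive displacement vectors
#' `d_t = x_{t+1} - x_t` of consecutive observed frames; triples spanning a
#' gap are skipped. Steps shorter than `min_step` yield no angle: with
#' sub-resolution displacements the direction is dominated by localization
#' noise, and a zero-length step has no direction at all.
#'
#' @inheritParams centered_velocities
#' @param min_step Minimum step length in µm for a displacement to carry a
#'   direction (default 0.2).
#' @return A tibble `track_id`, `frame` (slot of the vertex position),
#'   `angle_deg`.
#' @export
turning_angles <- function(tracks, min_step = 0.2, acquisition = NULL) {
  if (nrow(tracks) == 0) {
    return(tibble(track_id = character(), frame = integer(),
                  angle_deg = numeric()))
  }
  out <- lapply(.split_tracks(tracks), function(df) {
    n <- nrow(df)
    empty <- tibble(track_id = character(), frame = integer(),
                    angle_deg = numeric())
    if (n < 3) return(empty)
    pos <- as.matrix(df[, c("x_um", "y_um", "z_um")])
    d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
    consec <- diff(df$frame) == 1L
    ok <- consec[-length(consec)] & consec[-1]
    if (!any(ok)) return(empty)
    d1 <- d[-nrow(d), , drop = FALSE]
    d2 <- d[-1, , drop = FALSE]
    n1 <- sqrt(rowSums(d1^2)); n2 <- sqrt(rowSums(d2^2))
    ok <- ok & n1 >= min_step & n2 >= min_step
    if (!any(ok)) return(empty)
    cosang <- rowSums(d1 * d2)[ok] / (n1[ok] * n2[ok])
    cosang <- pmin(1, pmax(-1, cosang))
    tibble(track_id = df$track_id[1], frame = df$frame[-c(1, n)][ok],
           angle_deg = acos(cosang) * 180 / pi)
  })
  bind_rows(out)
}

#' Ensemble mean squared displacement
#'
#' For every eligible track, the squared displacement from its first
#' observed position at each time lag, averaged across tracks per lag
#' (ensemble MSD, not time-averaged over sliding origins). Eligibility
#' follows the "tracked continuously" convention: a track contributes only
#' if its initial gap-free segment lasts at least `require_continuous`
#' minutes, and only slots inside that segment are used.
#'
#' @inheritParams centered_velocities
#' @param max_lag Largest lag in minutes; must be a multiple of the frame
#'   interval.
#' @param require_continuous Minimum initial gap-free duration in minutes
#'   (default 10); `NULL` disables the continuity requirement, in which case
#'   any observed slot contributes.
#' @return A tibble of class `msd_curve`: `lag_min`, `msd_um2`, `n_tracks`.
#' @export
msd_ensemble <- function(tracks, max_lag = 10, require_continuous = 10,
                         acquisition = NULL) {
  acq <- get_acquisition(tracks, acquisition)
  dt <- acq$frame_interval
  nl <- max_lag / dt
  if (abs(nl - round(nl)) > 1e-8) {
    abort("`max_lag` must be a multiple of the frame interval")
  }
  nl <- as.integer(round(nl))
  per <- lapply(.split_tracks(tracks), function(df) {
    g <- .track_grid(df)
    n <- length(g$frames)
    if (!is.null(require_continuous)) {
      run <- which(!g$observed)[1]
      run <- if (is.na(run)) n else run - 1L
      if ((run - 1L) * dt < require_continuous) return(NULL)
      use <- seq_len(run)
    } else {
      use <- which(g$observed)
    }
    lag_idx <- use - 1L
    keep <- lag_idx <= nl
    sq <- rowSums((g$pos[use[keep], , drop = FALSE] -
                     matrix(g$pos[1, ], sum(keep), 3L, byrow = TRUE))^2)
    tibble(lag = lag_idx[keep], sq = sq)
  })
  per <- bind_rows(per)
  if (nrow(per) == 0) {
    curve <- tibble(lag_min = numeric(), msd_um2 = numeric(),
                    n_tracks = integer())
  } else {
    curve <- per %>%
      group_by(.data$lag) %>%
      summarise(msd_um2 = mean(.data$sq), n_tracks = dplyr::n(),
                .groups = "drop") %>%
      mutate(lag_min = .data$lag * dt) %>%
      select("lag_min", "msd_um2", "n_tracks")
  }
  structure(curve, class = c("msd_curve", class(curve)))
}

#' Per-track motility summary
#'
#' One row per track with the classical motility metrics and the quantities
#' the eligibility filters act on: mean track speed, arrest coefficient,
#' duration, net (start-to-end) displacement, and the number of valid
#' centered-difference velocities.
#'
#' @inheritParams centered_velocities
#' @param arrest_threshold Arrest threshold in µm/min.
#' @return A tibble `track_id`, condition columns, `mean_speed_um_min`,
#'   `arrest_pct`, `duration_min`, `net_disp_um`, `n_valid_velocities`,
#'   `n_speeds`.
#' @export
track_metrics <- function(tracks, arrest_threshold = 2, acquisition = NULL) {
  acq <- get_acquisition(tracks, acquisition)
  base <- validate_tracks(tracks, acq)
  sp <- mean_track_speed(tracks, acq)
  ar <- arrest_coefficient(tracks, arrest_threshold, acq)
  cv <- centered_velocities(tracks, acq) %>%
    group_by(.data$track_id) %>%
    summarise(n_valid_velocities = sum(.data$valid), .groups = "drop")
  net <- bind_rows(lapply(.split_tracks(tracks), function(df) {
    p <- as.matrix(df[, c("x_um", "y_um", "z_um")])
    tibble(track_id = df$track_id[1],
           net_disp_um = sqrt(sum((p[nrow(p), ] - p[1, ])^2)))
  }))
  conds <- track_conditions(tracks)
  out <- base %>%
    select("track_id", "duration_min") %>%
    left_join(select(sp, "track_id", "mean_speed_um_min", "n_speeds"),
              by = "track_id") %>%
    left_join(select(ar, "track_id", "arrest_pct"), by = "track_id") %>%
    left_join(net, by = "track_id") %>%
    left_join(cv, by = "track_id")
  if (length(conds) > 0) {
    lab <- distinct(as_tibble(tracks)[, c("track_id", conds)], .data$track_id,
                    .keep_all = TRUE)
    out <- left_join(out, lab, by = "track_id")
  }
  out[, c("track_id", conds, "mean_speed_um_min", "arrest_pct",
          "duration_min", "net_disp_um", "n_valid_velocities", "n_speeds")]
}
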