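#' Track eligibility policy
#'
#' Thresholds a track must meet to enter an analysis. Any criterion set to
#' `NULL` is inactive.
#'
#' @param min_duration Minimum duration in minutes (span of the frame grid).
#' @param min_displacement Minimum net start-to-end displacement in µm, or
#'   `NULL`. (Net displacement, not path length.)
#' @param min_valid_velocities Minimum number of valid centered-difference
#'   velocities, or `NULL`.
#' @param require_continuous Minimum gap-free stretch in minutes, or `NULL`.
#' @return An object of class `filter_policy`.
#' @seealso [filter_preset()] for the named policies used in practice.
#' @export
filter_policy <- function(min_duration = 0, min_displacement = NULL,
                          min_valid_velocities = NULL,
                          require_continuous = NULL) {
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || x < 0)) {
      abort(paste0("`", nm, "` must be NULL or a non-negative number"))
    }
  }
  chk(min_duration, "min_duration"); chk(min_displacement, "min_displacement")
  chk(min_valid_velocities, "min_valid_velocities")
  chk(require_continuous, "require_continuous")
  structure(list(min_duration = min_duration,
                 min_displacement = min_displacement,
                 min_valid_velocities = min_valid_velocities,
                 require_continuous = require_continuous),
            class = "filter_policy")
}

#' Named eligibility presets
#'
#' The eligibility rules used by the analyses this package reproduces:
#' * `"speed_2d3d"` — tracked at least 4 min and net displacement at least
#'   15 µm (speed comparisons on 2D surfaces and in collagen).
#' * `"blebbistatin"` — minimum duration 4 min only (myosin-inhibitor
#'   experiments, where arrested cells must not be excluded by a
#'   displacement floor).
#' * `"clustering"` — tracked at least 240 s and at least 15 valid velocity
#'   measurements (eligibility for random-walk parameter inference and
#'   sub-population clustering).
#' * `"invivo"` — tracked at least 5 min (lymph-node imaging).
#'
#' @param name Preset name.
#' @return A [filter_policy()].
#' @export
filter_preset <- function(name = c("speed_2d3d", "blebbistatin",
                                   "clustering", "invivo")) {
  name <- match.arg(name)
  switch(name,
    speed_2d3d = filter_policy(min_duration = 4, min_displacement = 15),
    blebbistatin = filter_policy(min_duration = 4),
    clustering = filter_policy(min_duration = 4, min_valid_velocities = 15),
    invivo = filter_policy(min_duration = 5)
  )
}

#' Apply an eligibility policy to a track table
#'
#' Removes tracks failing any active criterion and logs, per excluded track,
#' every criterion it failed.
#'
#' @param tracks A track table.
#' @param policy A [filter_policy()] or a preset name (see
#'   [filter_preset()]).
#' @param acquisition Optional [acquisition_spec()] override.
#' @return A list: `tracks` (the retained track table), `exclusions`
#'   (tibble `track_id`, `reason`, one row per failed criterion), and
#'   `counts` (`n_in`, `n_kept`, `n_excluded`).
#' @examples
#' cfg <- simulation_config(n_cells = 12, seed = 3)
#' co <- simulate_cohort(cfg)
#' res <- apply_track_filters(co$tracks, "clustering")
#' res$counts
#' @export
apply_track_filters <- function(tracks, policy = filter_preset("speed_2d3d"),
                                acquisition = NULL) {
  if (is.character(policy)) policy <- filter_preset(policy)
  stopifnot(inherits(policy, "filter_policy"))
  acq <- get_acquisition(tracks, acquisition)
  m <- track_metrics(tracks, acquisition = acq)
  dt <- acq$frame_interval
  fail <- list()
  add <- function(ids, reason) {
    if (length(ids) > 0) {
      fail[[length(fail) + 1]] <<- tibble(track_id = ids, reason = reason)
    }
  }
  add(m$track_id[m$duration_min < policy$min_duration],
      sprintf("duration < %g min", policy$min_duration))
  if (!is.null(policy$min_displacement)) {
    add(m$track_id[m$net_disp_um < policy$min_displacement],
        sprintf("net displacement < %g um", policy$min_displacement))
  }
  if (!is.null(policy$min_valid_velocities)) {
    add(m$track_id[m$n_valid_velocities < policy$min_valid_velocities],
        sprintf("valid velocities < %g", policy$min_valid_velocities))
  }
  if (!is.null(policy$require_continuous)) {
    runs <- vapply(.split_tracks(tracks), function(df) {
      g <- .track_grid(df)
      r <- rle(g$observed)
      max(c(0L, r$lengths[r$values])) - 1L
    }, integer(1))
    ids <- names(runs)[runs * dt < policy$require_continuous]
    add(ids, sprintf("no continuous stretch >= %g min",
                     policy$require_continuous))
  }
  exclusions <- if (length(fail) > 0) bind_rows(fail) else {
    tibble(track_id = character(), reason = character())
  }
  drop_ids <- unique(exclusions$track_id)
  kept <- as_tibble(tracks)[!tracks$track_id %in% drop_ids, , drop = FALSE]
  kept <- as_track_tbl(kept, acquisition = acq,
                       provenance = attr(tracks, "provenance"))
  list(tracks = kept, exclusions = exclusions,
       counts = c(n_in = length(unique(tracks$track_id)),
                  n_kept = length(unique(kept$track_id)),
                  n_excluded = length(drop_ids)))
}
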