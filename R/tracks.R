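# Core column set of a track table; everything else is either a condition
# label or a reserved simulator column.
.track_core_cols <- c("track_id", "frame", "t_min", "x_um", "y_um", "z_um")
.track_reserved_cols <- c("ux_true_um_min", "uy_true_um_min", "uz_true_um_min")

#' Build a track table from a data frame of tracked positions
#'
#' A track table is a tidy tibble with one row per observed (cell, frame)
#' pair: columns `track_id`, `frame` (integer index on the regular
#' acquisition grid), `t_min`, `x_um`, `y_um`, `z_um`, plus any number of
#' condition columns (genotype, treatment, matrix density, ...). Frames that
#' were not observed are simply absent; gaps are recovered from the missing
#' frame indices.
#'
#' @param df Data frame with at least `track_id`, `frame`, `x_um`, `y_um`,
#'   `z_um`. `t_min` is recomputed from the frame index.
#' @param acquisition An [acquisition_spec()].
#' @param provenance Optional free-text metadata (source file, seed, ...).
#'
#' @return A tibble of class `track_tbl` sorted by track and frame, with the
#'   acquisition spec attached as an attribute.
#' @examples
#' df <- data.frame(track_id = "c1", frame = 0:2,
#'                  x_um = c(0, 1, 2), y_um = 0, z_um = 0)
#' as_track_tbl(df)
#' @export
as_track_tbl <- function(df, acquisition = acquisition_spec(),
                         provenance = NULL) {
  stopifnot(is.data.frame(df), inherits(acquisition, "acquisition_spec"))
  need <- setdiff(c("track_id", "frame", "x_um", "y_um", "z_um"), names(df))
  if (length(need) > 0) {
    abort(paste0("missing required column(s): ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$track_id <- as.character(out$track_id)
  out$frame <- as.integer(out$frame)
  pos <- as.matrix(out[, c("x_um", "y_um", "z_um")])
  if (nrow(out) > 0 && !all(is.finite(pos))) {
    abort("positions must be finite")
  }
  if (anyDuplicated(out[, c("track_id", "frame")])) {
    abort("duplicate (track_id, frame) rows")
  }
  out$t_min <- (out$frame - acquisition$time_origin) * acquisition$frame_interval
  extra <- setdiff(names(out), .track_core_cols)
  out <- out[, c(.track_core_cols, extra)]
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  structure(out,
            class = c("track_tbl", class(as_tibble(out))),
            acquisition = acquisition,
            provenance = provenance)
}

#' Names of the condition columns of a track table
#'
#' @param tracks A track table.
#' @return Character vector of condition column names (may be empty).
#' @export
track_conditions <- function(tracks) {
  setdiff(names(tracks), c(.track_core_cols, .track_reserved_cols))
}

#' Per-track validation report
#'
#' Lists, for every track, the observed-slot count, the span on the frame
#' grid, the duration in minutes, and the number of gaps (frames inside the
#' span with no observation). Zero-length tracks (a single observation) are
#' flagged rather than treated as errors.
#'
#' @param tracks A track table.
#' @param acquisition Optional [acquisition_spec()] override.
#' @return A tibble with one row per track: `track_id`, `n_obs`,
#'   `first_frame`, `last_frame`, `duration_min`, `n_gaps`, `zero_length`.
#' @export
validate_tracks <- function(tracks, acquisition = NULL) {
  acq <- get_acquisition(tracks, acquisition)
  if (nrow(tracks) == 0) {
    return(tibble(track_id = character(), n_obs = integer(),
                  first_frame = integer(), last_frame = integer(),
                  duration_min = numeric(), n_gaps = integer(),
                  zero_length = logical()))
  }
  tracks %>%
    group_by(.data$track_id) %>%
    summarise(
      n_obs = dplyr::n(),
      first_frame = min(.data$frame),
      last_frame = max(.data$frame),
      duration_min = (max(.data$frame) - min(.data$frame)) * acq$frame_interval,
      n_gaps = (max(.data$frame) - min(.data$frame) + 1L) - dplyr::n(),
      zero_length = dplyr::n() < 2L,
      .groups = "drop"
    )
}

# Split a track table into a named list of per-track data frames,
# preserving input track order of first appearance.
.split_tracks <- function(tracks) {
  split(as_tibble(tracks), factor(tracks$track_id, levels = unique(tracks$track_id)))
}

# Regularized frame grid of one track: positions matrix with NA at gaps.
.track_grid <- function(df) {
  f0 <- min(df$frame); f1 <- max(df$frame)
  frames <- f0:f1
  idx <- match(frames, df$frame)
  pos <- matrix(NA_real_, length(frames), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  obs <- !is.na(idx)
  pos[obs, ] <- as.matrix(df[idx[obs], c("x_um", "y_um", "z_um")])
  list(frames = frames, observed = obs, pos = pos)
}
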