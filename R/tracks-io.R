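#' Column-mapping dialect for trajectory CSV files
#'
#' Maps the column headers of a foreign position export (e.g. a commercial
#' tracker's `TrackID,Time,Position X` layout) onto the roles the package
#' needs. Exactly one of a frame column or a time column must be mapped;
#' timestamps are snapped to the nearest frame on the regular grid.
#'
#' @param track_id,x,y,z Column names holding the track identifier and the
#'   positions (micrometres).
#' @param frame Column name holding an integer frame index, or `NULL` when
#'   time is given instead.
#' @param time Column name holding a timestamp, or `NULL` when `frame` is
#'   given. Interpreted in `time_unit`.
#' @param time_unit `"min"` or `"s"`; timestamps in seconds are converted to
#'   minutes before snapping.
#' @param conditions Character vector of column names to carry along as
#'   condition labels. `NULL` keeps every unmapped column.
#'
#' @return An object of class `track_dialect`.
#' @examples
#' track_dialect()  # native layout
#' track_dialect(track_id = "TrackID", time = "Time", time_unit = "s",
#'               x = "Position X", y = "Position Y", z = "Position Z")
#' @export
track_dialect <- function(track_id = "track_id", frame = "frame", time = NULL,
                          x = "x_um", y = "y_um", z = "z_um",
                          time_unit = c("min", "s"), conditions = NULL) {
  time_unit <- match.arg(time_unit)
  if (is.null(frame) && is.null(time)) {
    abort("dialect must map either a `frame` or a `time` column")
  }
  structure(list(track_id = track_id, frame = frame, time = time,
                 x = x, y = y, z = z, time_unit = time_unit,
                 conditions = conditions),
            class = "track_dialect")
}

#' Read a trajectory CSV into a track table
#'
#' Reads a table of tracked 3D positions, maps columns through `dialect`,
#' snaps timestamps to the regular frame grid, and returns one track per
#' distinct identifier. Frames absent from the file become gaps.
#'
#' @param path Path to a CSV file.
#' @param dialect A [track_dialect()] describing the column layout.
#' @param acquisition An [acquisition_spec()]; sets the frame interval used
#'   for timestamp snapping and the `t_min` column.
#' @param constants Optional named character vector of condition labels to
#'   attach to every row (e.g. `c(genotype = "WT")`).
#'
#' @return A `track_tbl` (see [as_track_tbl()]).
#' @details Timestamps deviating from the grid by more than 25% of the frame
#'   interval are an error rather than a new frame: regular-grid acquisitions
#'   jitter, they do not interleave. Duplicate (track, frame) rows are also
#'   an error.
#' @export
read_tracks <- function(path, dialect = track_dialect(),
                        acquisition = acquisition_spec(), constants = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c(track_id = dialect$track_id, x = dialect$x, y = dialect$y,
              z = dialect$z)
  if (!is.null(dialect$frame)) needed <- c(needed, frame = dialect$frame)
  if (!is.null(dialect$time)) needed <- c(needed, time = dialect$time)
  miss <- needed[!needed %in% names(raw)]
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  df <- tibble(
    track_id = as.character(raw[[dialect$track_id]]),
    x_um = as.numeric(raw[[dialect$x]]),
    y_um = as.numeric(raw[[dialect$y]]),
    z_um = as.numeric(raw[[dialect$z]])
  )
  if (!is.null(dialect$frame) && dialect$frame %in% names(raw)) {
    df$frame <- as.integer(raw[[dialect$frame]])
  } else {
    t_min <- as.numeric(raw[[dialect$time]])
    if (dialect$time_unit == "s") t_min <- t_min / 60
    rel <- t_min / acquisition$frame_interval
    fr <- round(rel)
    dev <- abs(rel - fr)
    if (any(dev > 0.25)) {
      bad <- which(dev > 0.25)[1]
      abort(paste0("timestamp ", t_min[bad], " min deviates from the frame grid ",
                   "by more than 25% of the frame interval (",
                   acquisition$frame_interval, " min)"))
    }
    df$frame <- as.integer(fr) + acquisition$time_origin
  }
  cond_cols <- dialect$conditions
  if (is.null(cond_cols)) {
    cond_cols <- setdiff(names(raw), c(unname(needed), "t_min"))
  }
  for (cc in cond_cols) df[[cc]] <- raw[[cc]]
  if (!is.null(constants)) {
    for (nm in names(constants)) df[[nm]] <- constants[[nm]]
  }
  as_track_tbl(df, acquisition = acquisition,
               provenance = paste0("read_tracks: ", path))
}

#' Write a track table to CSV
#'
#' Writes the native layout `track_id,frame,t_min,x_um,y_um,z_um` plus any
#' condition columns. Gap slots are simply not emitted; reading the file back
#' with [read_tracks()] reproduces observed frames and positions exactly.
#'
#' @param tracks A track table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c(.track_core_cols, track_conditions(tracks))
  out <- as_tibble(tracks)[, intersect(cols, names(tracks)), drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
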