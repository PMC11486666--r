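#' Acquisition settings for a tracking experiment
#'
#' Describes the regular temporal grid on which positions were acquired.
#' Two-photon / confocal volumetric time-lapse imaging of migrating cells is
#' typically acquired at a fixed frame interval (about one stack every 30 s,
#' i.e. 0.5 min); all internal units are micrometres and minutes.
#'
#' @param frame_interval Time between consecutive frames, in minutes.
#'   Must be > 0. Default 0.5 (a stack every 30 s).
#' @param position_units Label for the position units; fixed to `"um"`.
#' @param time_origin Frame index of the first frame on the grid (0-based).
#'
#' @return An object of class `acquisition_spec`.
#' @examples
#' acquisition_spec()                 # 30 s frames
#' acquisition_spec(frame_interval = 1/3)  # 20 s frames
#' @export
acquisition_spec <- function(frame_interval = 0.5, position_units = "um",
                             time_origin = 0L) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be a single positive number (minutes).")
  }
  if (!identical(position_units, "um")) {
    abort("`position_units` is fixed to \"um\".")
  }
  structure(
    list(frame_interval = as.numeric(frame_interval),
         position_units = "um",
         time_origin = as.integer(time_origin)),
    class = "acquisition_spec"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat("<acquisition_spec> frame_interval =", x$frame_interval,
      "min, units =", x$position_units,
      ", time_origin =", x$time_origin, "\n")
  invisible(x)
}

# Resolve the acquisition spec for a track table: explicit argument wins,
# then the attribute attached by as_track_tbl(); as a last resort the frame
# interval is recovered from the t_min/frame columns (dplyr verbs drop
# attributes, so tables that went through a pipe still carry their clock in
# the t_min column).
get_acquisition <- function(tracks, acquisition = NULL) {
  if (!is.null(acquisition)) {
    stopifnot(inherits(acquisition, "acquisition_spec"))
    return(acquisition)
  }
  att <- attr(tracks, "acquisition", exact = TRUE)
  if (inherits(att, "acquisition_spec")) return(att)
  if (is.data.frame(tracks) && all(c("frame", "t_min") %in% names(tracks)) &&
      nrow(tracks) > 0) {
    ok <- tracks$frame != 0
    if (any(ok)) {
      dt <- stats::median(tracks$t_min[ok] / tracks$frame[ok])
      if (is.finite(dt) && dt > 0) return(acquisition_spec(frame_interval = dt))
    }
  }
  acquisition_spec()
}
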