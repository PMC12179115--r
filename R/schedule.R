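#' Dynamic PET frame schedules
#'
#' A frame schedule is the ordered sequence of acquisition time bins of a
#' dynamic PET scan, in minutes post injection (injection at t = 0).  At most
#' one frame -- a pre-injection background frame -- may start before 0.
#'
#' @param counts integer vector, number of consecutive frames per block.
#' @param durations numeric vector (same length), duration of each frame in
#'   the block.
#' @param units `"s"` or `"min"` for `durations`.
#' @param background optional background frame duration (same units), placed
#'   immediately before injection (ends at t = 0).
#' @return A data frame of class `"frame_schedule"` with columns `start` and
#'   `end` (minutes).
#' @examples
#' sched <- frame_schedule(c(4, 7, 2), c(1, 5, 10), units = "min")
#' sum(frame_durations(sched))
#' @export
frame_schedule <- function(counts, durations, units = c("s", "min"),
                           background = NULL) {
  units <- match.arg(units)
  if (length(counts) != length(durations))
    stop("`counts` and `durations` must have the same length")
  if (any(counts < 1) || any(counts != round(counts)))
    stop("`counts` must be positive integers")
  if (any(durations <= 0))
    stop("frame durations must be strictly positive")
  dur <- rep(durations, counts)
  if (units == "s") dur <- dur / 60
  end <- cumsum(dur)
  start <- c(0, end[-length(end)])
  if (!is.null(background)) {
    if (background <= 0) stop("background duration must be positive")
    bg <- if (units == "s") background / 60 else background
    start <- c(-bg, start)
    end <- c(0, end)
  }
  new_frame_schedule(start, end)
}

new_frame_schedule <- function(start, end) {
  sched <- data.frame(start = as.numeric(start), end = as.numeric(end))
  validate_frame_schedule(sched)
  class(sched) <- c("frame_schedule", "data.frame")
  sched
}

validate_frame_schedule <- function(sched) {
  if (nrow(sched) == 0) stop("schedule has no frames")
  if (any(sched$end <= sched$start))
    stop("every frame must satisfy end > start")
  if (nrow(sched) > 1) {
    if (any(diff(sched$start) <= 0) ||
        any(sched$start[-1] < sched$end[-nrow(sched)]))
      stop("frames must be non-overlapping and strictly increasing")
  }
  if (sum(sched$start < 0) > 1)
    stop("at most one (background) frame may start before t = 0")
  invisible(sched)
}

#' @rdname frame_schedule
#' @param sched a `frame_schedule`.
#' @export
frame_durations <- function(sched) sched$end - sched$start

#' @rdname frame_schedule
#' @export
frame_midpoints <- function(sched) (sched$start + sched$end) / 2

#' Printed acquisition schedules of the two imaging centres
#'
#' `manchester_schedule()` returns the 18-frame schedule (one ~6-min
#' pre-injection background frame; 1x15 s, 1x5 s, 1x10 s, 1x30 s, 4x1 min,
#' 7x5 min, 2x10 min); `turku_schedule()` the 17-frame schedule (2x15 s,
#' 3x30 s, 3x1 min, 7x5 min, 2x10 min).  Both cover 60 minutes post
#' injection.
#'
#' @param background include the Manchester pre-injection background frame.
#' @return a [frame_schedule].
#' @export
manchester_schedule <- function(background = TRUE) {
  frame_schedule(counts = c(1, 1, 1, 1, 4, 7, 2),
                 durations = c(15, 5, 10, 30, 60, 300, 600),
                 units = "s",
                 background = if (background) 360 else NULL)
}

#' @rdname manchester_schedule
#' @export
turku_schedule <- function() {
  frame_schedule(counts = c(2, 3, 3, 7, 2),
                 durations = c(15, 30, 60, 300, 600),
                 units = "s")
}

#' Default per-frame fitting weights
#'
#' Frame-duration weights (variance of decay-corrected frame means scales as
#' 1/duration under the frame-count noise model); background frames always
#' get weight 0 and are excluded from fits.
#'
#' @param sched a [frame_schedule].
#' @param type `"duration"` (default) or `"uniform"`.
#' @return numeric vector, one weight per frame.
#' @export
default_weights <- function(sched, type = c("duration", "uniform")) {
  type <- match.arg(type)
  w <- switch(type,
              duration = frame_durations(sched),
              uniform = rep(1, nrow(sched)))
  w[sched$start < 0] <- 0
  w
}
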