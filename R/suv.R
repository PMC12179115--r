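#' Windowed standardized uptake value
#'
#' Averages the radioactivity concentration over the frames intersecting a
#' time window (duration-of-overlap weighted), then normalises by injected
#' activity per body weight:
#' `SUV = mean_conc [kBq/mL] * weight [kg] / activity [MBq]`, dimensionless
#' under an assumed tissue density of 1 g/mL.  The conventional late window
#' for this tracer is 40--60 minutes.
#'
#' @param x a [tac].
#' @param injected_activity injected activity (MBq), positive.
#' @param body_weight body weight (kg), positive.
#' @param window numeric length 2, window start/end in minutes.
#' @return a list of class `"suv_value"` with fields `value` and `window`.
#' @examples
#' sch <- turku_schedule()
#' suv_window(tac(sch, rep(1, nrow(sch))), 500, 70)$value  # 70/500
#' @export
suv_window <- function(x, injected_activity, body_weight, window = c(40, 60)) {
  stopifnot(inherits(x, "tac"))
  if (length(window) != 2 || window[2] <= window[1])
    stop("`window` must be (start, end) with end > start")
  if (injected_activity <= 0) stop("`injected_activity` must be positive")
  if (body_weight <= 0) stop("`body_weight` must be positive")
  ov <- pmin(x$schedule$end, window[2]) - pmax(x$schedule$start, window[1])
  ov <- pmax(ov, 0)
  if (sum(ov) == 0) stop("no frame overlaps the window [",
                         window[1], ", ", window[2], "] min")
  mean_conc <- sum(ov * x$values) / sum(ov)
  structure(list(value = mean_conc * body_weight / injected_activity,
                 window = window, mean_conc = mean_conc),
            class = "suv_value")
}

#' @export
print.suv_value <- function(x, ...) {
  cat(sprintf("SUV[%g-%g min] = %.4f\n", x$window[1], x$window[2], x$value))
  invisible(x)
}
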