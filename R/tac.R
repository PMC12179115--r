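#' Time-activity curves
#'
#' A time-activity curve (TAC) holds one decay-corrected radioactivity
#' concentration (kBq/mL) per frame of a [frame_schedule].
#'
#' @param schedule a [frame_schedule].
#' @param values numeric vector, one finite value per frame.
#' @param label optional region/side tag.
#' @return an object of class `"tac"`.
#' @export
tac <- function(schedule, values, label = NULL) {
  validate_frame_schedule(schedule)
  values <- as.numeric(values)
  if (length(values) != nrow(schedule))
    stop("need exactly one value per frame (", nrow(schedule), " frames, ",
         length(values), " values)")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values, label = label),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat("Time-activity curve", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "\n", sep = " ")
  cat("  frames:", nrow(x$schedule), " span:",
      sprintf("%.2f to %.2f min", min(x$schedule$start), max(x$schedule$end)),
      "\n")
  cat("  peak:", sprintf("%.3f kBq/mL", max(x$values)), "\n")
  invisible(x)
}

#' Bi-exponential reference input
#'
#' Continuous surge-and-washout curve
#' `C(t) = amp * (exp(-lam1 * t) - exp(-lam2 * t))` for `t >= 0` (0 before
#' injection), the simplest shape with a realistic peak-then-washout and a
#' closed-form peak time `log(lam2/lam1) / (lam2 - lam1)`.
#'
#' @param amp concentration scale (kBq/mL), positive.
#' @param lam1 slow rate constant (1/min), positive.
#' @param lam2 fast rate constant (1/min), must exceed `lam1`.
#' @return a function of time (minutes), vectorised.
#' @export
biexp_input <- function(amp, lam1, lam2) {
  check_biexp(amp, lam1, lam2)
  function(t) ifelse(t > 0, amp * (exp(-lam1 * t) - exp(-lam2 * t)), 0)
}

check_biexp <- function(amp, lam1, lam2) {
  if (amp <= 0) stop("`amp` must be positive")
  if (lam1 <= 0) stop("`lam1` must be positive")
  if (lam2 <= lam1) stop("`lam2` must exceed `lam1` (no surge shape otherwise)")
  invisible(TRUE)
}

#' Simulate a reference-region TAC
#'
#' Frame-averages the bi-exponential input of [biexp_input] analytically over
#' each frame of `schedule` (exact integral, no quadrature).  Frames entirely
#' before injection read 0.
#'
#' @inheritParams biexp_input
#' @param schedule a [frame_schedule].
#' @param label region tag for the returned TAC.
#' @return a [tac].
#' @export
simulate_reference_tac <- function(schedule, amp = 30, lam1 = 0.05,
                                   lam2 = 0.5, label = "cerebellum_gm") {
  check_biexp(amp, lam1, lam2)
  lo <- pmax(schedule$start, 0)
  hi <- pmax(schedule$end, 0)
  # integral of exp(-l t) on [lo, hi]
  int <- function(l) (exp(-l * lo) - exp(-l * hi)) / l
  vals <- amp * (int(lam1) - int(lam2)) / frame_durations(schedule)
  vals[hi <= lo] <- 0
  tac(schedule, vals, label = label)
}

#' Add frame-variance noise to a TAC
#'
#' Gaussian noise with standard deviation
#' `sigma_j = alpha * sqrt(max(value_j, floor) / dt_j)` where `dt_j` is the
#' frame duration in minutes -- the standard variance model for
#' decay-corrected frame means (shorter, hotter frames are noisier).
#' Negative outputs are allowed, as for real decay-corrected PET data.
#'
#' @param x a [tac].
#' @param alpha noise scale, `>= 0`; 0 returns the input unchanged.
#' @param seed integer seed; the draw is deterministic given `(x, alpha, seed)`
#'   and does not disturb the caller's RNG state.
#' @param floor small positive value bounding the variance away from zero.
#' @return a [tac] with perturbed values.
#' @export
add_tac_noise <- function(x, alpha, seed, floor = 0.1) {
  stopifnot(inherits(x, "tac"))
  if (alpha < 0) stop("`alpha` must be non-negative")
  if (alpha == 0) return(x)
  sigma <- alpha * sqrt(pmax(x$values, floor) / frame_durations(x$schedule))
  eps <- with_seed(seed, stats::rnorm(length(sigma), 0, sigma))
  tac(x$schedule, x$values + eps, label = x$label)
}
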