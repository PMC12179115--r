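#' SRTM kinetic parameters
#'
#' The simplified reference tissue model (SRTM) describes a target-region TAC
#' as a function of a reference-region TAC through three parameters: the
#' tracer delivery ratio `R1 = K1/K1'` (target over reference influx; the
#' individual K1s never appear separately), the target efflux rate `k2`
#' (1/min) and the non-displaceable binding potential `BP_ND`.  Two derived
#' quantities are carried along: the apparent efflux `k2a = k2/(1 + BP_ND)`
#' and the distribution volume ratio `DVR = BP_ND + 1`.
#'
#' @param R1 tracer delivery ratio (unitless).
#' @param k2 target efflux rate constant (1/min), positive.
#' @param BP_ND non-displaceable binding potential (unitless), `> -1`.
#' @return an object of class `"srtm_params"`.
#' @export
srtm_params <- function(R1, k2, BP_ND) {
  if (BP_ND <= -1) stop("`BP_ND` must exceed -1 (k2a undefined otherwise)")
  if (k2 <= 0) stop("`k2` must be positive")
  structure(list(R1 = R1, k2 = k2, BP_ND = BP_ND,
                 k2a = k2 / (1 + BP_ND), DVR = BP_ND + 1),
            class = "srtm_params")
}

#' @export
print.srtm_params <- function(x, ...) {
  cat(sprintf("SRTM parameters: R1 = %.4f, k2 = %.4f /min, BP_ND = %.4f (DVR = %.4f, k2a = %.4f /min)\n",
              x$R1, x$k2, x$BP_ND, x$DVR, x$k2a))
  invisible(x)
}

#' SRTM forward model
#'
#' Operational solution
#' `C_T(t) = R1 * C_R(t) + (k2 - R1 * k2a) * int_0^t C_R(s) exp(-k2a (t-s)) ds`.
#' The reference curve is treated as piecewise linear (through frame
#' midpoints with value 0 at t <= 0 when a measured [tac] is supplied, or a
#' dense sampling when a function is supplied) and the convolution is
#' evaluated analytically per linear segment; the returned TAC holds exact
#' frame averages of the convolution term.  When `ref` is a [tac] the direct
#' `R1 * C_R` term uses the measured frame values, so `R1 = 1, BP_ND = 0`
#' reproduces the reference frame-for-frame.
#'
#' @param params an [srtm_params].
#' @param ref reference input: a [tac] or a function of time (minutes).
#' @param schedule output [frame_schedule]; defaults to `ref$schedule` when
#'   `ref` is a TAC.
#' @param label tag for the returned TAC.
#' @param n_grid sampling density used when `ref` is a function.
#' @return a [tac] of model values.
#' @seealso [srtm_curve] for pointwise continuous-time evaluation.
#' @export
srtm_forward <- function(params, ref, schedule = NULL, label = NULL,
                         n_grid = 1024) {
  stopifnot(inherits(params, "srtm_params"))
  if (inherits(ref, "tac")) {
    schedule <- schedule %||% ref$schedule
    knots <- pl_knots_from_tac(ref)
    ref_frames <- ref$values
  } else if (is.function(ref)) {
    if (is.null(schedule)) stop("`schedule` is required when `ref` is a function")
    knots <- pl_knots_from_fun(ref, max(schedule$end),
                               breaks = c(schedule$start, schedule$end),
                               n_grid = n_grid)
    ref_frames <- pl_frame_avg(knots, schedule)
  } else stop("`ref` must be a `tac` or a function of time")
  conv <- drop(conv_exp_frame_avg(knots, params$k2a, schedule))
  vals <- params$R1 * ref_frames + (params$k2 - params$R1 * params$k2a) * conv
  tac(schedule, vals, label = label)
}

#' Pointwise SRTM model curve
#'
#' Continuous-time evaluation of the SRTM operational solution at arbitrary
#' times, used to check the model against closed-form solutions (for a unit
#' step reference, `C_T(t) = R1 + (k2 - R1 k2a)(1 - exp(-k2a t))/k2a`, whose
#' plateau is the DVR).
#'
#' @inheritParams srtm_forward
#' @param times evaluation times (minutes, `>= 0`).
#' @return numeric vector of model values.
#' @export
srtm_curve <- function(params, ref, times, n_grid = 4096) {
  stopifnot(inherits(params, "srtm_params"), is.function(ref))
  knots <- pl_knots_from_fun(ref, max(times), breaks = times, n_grid = n_grid)
  params$R1 * ref(times) +
    (params$k2 - params$R1 * params$k2a) * conv_exp_at(knots, params$k2a, times)
}

#' Logarithmic k2a search grid for the basis-function fitter
#'
#' 256 logarithmically spaced apparent-efflux values on [0.005, 1.0] /min,
#' bracketing plausible PK11195 kinetics with near-continuous resolution.
#'
#' @param n grid size.
#' @param lower,upper grid range (1/min).
#' @export
srtm_k2a_grid <- function(n = 256, lower = 0.005, upper = 1.0) {
  if (lower <= 0 || upper <= lower) stop("need 0 < lower < upper")
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Precompute the SRTM basis matrix
#'
#' Frame-averaged convolution of the reference TAC with `exp(-k2a_i t)` for
#' every grid value (one row per k2a).  The basis depends only on the
#' reference and the grid, so it can be computed once per subject and shared
#' by every target-region fit via the `basis` argument of [fit_srtm].
#'
#' @inheritParams fit_srtm
#' @return numeric matrix, `length(grid)` rows by `n_frames` columns.
#' @export
srtm_basis <- function(ref, grid = srtm_k2a_grid()) {
  stopifnot(inherits(ref, "tac"))
  conv_exp_frame_avg(pl_knots_from_tac(ref), grid, ref$schedule)
}

# Weighted 2-parameter LLS of target on (ref, basis row); returns theta and
# weighted RSS for every grid row at once.
basis_lls <- function(target_v, ref_v, B, w) {
  Srr <- sum(w * ref_v^2)
  Srt <- sum(w * ref_v * target_v)
  Stt <- sum(w * target_v^2)
  Srb <- drop(B %*% (w * ref_v))
  Sbt <- drop(B %*% (w * target_v))
  Sbb <- drop((B * B) %*% w)
  det <- Srr * Sbb - Srb^2
  bad <- !is.finite(det) | det <= .Machine$double.eps * Srr * Sbb
  th2 <- (Srr * Sbt - Srb * Srt) / det
  th1 <- (Srt - th2 * Srb) / Srr
  wrss <- Stt - 2 * th1 * Srt - 2 * th2 * Sbt +
    th1^2 * Srr + 2 * th1 * th2 * Srb + th2^2 * Sbb
  th1[bad] <- Srt / Srr
  th2[bad] <- 0
  wrss[bad] <- Stt - Srt^2 / max(Srr, .Machine$double.xmin)
  list(theta1 = th1, theta2 = th2, wrss = pmax(wrss, 0), Stt = Stt, Srr = Srr)
}

#' Fit the simplified reference tissue model
#'
#' Basis-function fit: for each apparent-efflux value `k2a_i` on a
#' logarithmic grid, the convolution basis
#' `B_i = C_R (x) exp(-k2a_i t)` is precomputed analytically and the
#' two-parameter weighted linear least-squares problem
#' `C_T ~ theta1 * C_R + theta2 * B_i` solved in closed form; the grid value
#' minimising the weighted residual sum of squares wins and is then sharpened
#' by golden-section search between its neighbours.  Parameters map back as
#' `R1 = theta1`, `k2 = theta2 + theta1 * k2a`, `BP_ND = k2/k2a - 1`.
#' Background frames are excluded (weight 0).
#'
#' @param target target-region [tac].
#' @param ref reference-region [tac] on the same schedule.
#' @param weights per-frame weights; default duration weights
#'   ([default_weights]).
#' @param grid sorted positive k2a search grid ([srtm_k2a_grid]).
#' @param refine golden-section refinement of the winning grid interval.
#' @param basis optional precomputed [srtm_basis] for `ref` and `grid`
#'   (reused across the many target regions of one subject).
#' @return an object of class `"srtm_fit"`: the [srtm_params], `wrss`,
#'   `weights`, the selected `k2a`, and `boundary`/`degenerate` flags.  A
#'   degenerate fit (target proportional to the reference, or all zero)
#'   reports `BP_ND = 0` with `degenerate = TRUE` since `k2` is then
#'   unidentifiable; boundary solutions are flagged, never clamped.
#' @examples
#' sch <- turku_schedule()
#' ref <- simulate_reference_tac(sch)
#' tc <- srtm_forward(srtm_params(1.2, 0.1, 0.2), ref)
#' fit <- fit_srtm(tc, ref)
#' coef(fit)
#' @export
fit_srtm <- function(target, ref, weights = NULL, grid = srtm_k2a_grid(),
                     refine = TRUE, basis = NULL) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!isTRUE(all.equal(target$schedule, ref$schedule, check.attributes = FALSE)))
    stop("target and reference must share one frame schedule")
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0))
    stop("`grid` must be strictly positive and sorted")
  weights <- weights %||% default_weights(target$schedule)
  w <- weights
  w[target$schedule$start < 0] <- 0
  if (sum(w > 0) < 3) stop("need at least 3 weighted post-injection frames")
  if (is.null(basis)) basis <- srtm_basis(ref, grid)

  y <- target$values
  r <- ref$values
  sol <- basis_lls(y, r, basis, w)

  if (sol$Stt == 0 || sol$Srr == 0) {     # all-zero target (or reference)
    params <- structure(list(R1 = 0, k2 = 0, BP_ND = 0, k2a = grid[1], DVR = 1),
                        class = "srtm_params")
    return(new_srtm_fit(params, wrss = 0, weights = w, k2a = grid[1],
                        boundary = FALSE, degenerate = TRUE,
                        target = target, ref = ref, grid = grid))
  }

  i <- which.min(sol$wrss)
  boundary <- i == 1 || i == length(grid)
  k2a_hat <- grid[i]
  th1 <- sol$theta1[i]; th2 <- sol$theta2[i]; wrss <- sol$wrss[i]

  # target proportional to reference: every k2a fits equally well
  degenerate <- (max(sol$wrss) - min(sol$wrss)) <= 1e-12 * sol$Stt

  if (refine && !boundary && !degenerate) {
    # successive parabolic interpolation of wrss(log k2a) around the winner:
    # grid spacing is ~2% relative, so two parabola steps localise the
    # minimum far below the accuracy the parameters need
    knots <- pl_knots_from_tac(ref)
    obj <- function(lk2a) {
      b <- conv_exp_frame_avg(knots, exp(lk2a), target$schedule)
      s <- basis_lls(y, r, b, w)
      list(w = s$wrss, th1 = s$theta1, th2 = s$theta2)
    }
    px <- log(grid[(i - 1):(i + 1)])
    pw <- sol$wrss[(i - 1):(i + 1)]
    for (step in 1:2) {
      o <- order(px)
      x1 <- px[o[1]]; x2 <- px[o[2]]; x3 <- px[o[3]]
      ww <- pw[o]
      den <- (x2 - x1) * (ww[2] - ww[3]) - (x2 - x3) * (ww[2] - ww[1])
      if (!is.finite(den) || den == 0) break
      v <- x2 - 0.5 * ((x2 - x1)^2 * (ww[2] - ww[3]) -
                       (x2 - x3)^2 * (ww[2] - ww[1])) / den
      v <- min(max(v, min(px) + 1e-12), max(px) - 1e-12)
      if (any(abs(v - px) < 1e-12)) break
      s <- obj(v)
      if (s$w < wrss) {
        wrss <- s$w; k2a_hat <- exp(v); th1 <- s$th1; th2 <- s$th2
      }
      keep <- order(pw)[1:2]
      px <- c(px[keep], v); pw <- c(pw[keep], s$w)
    }
  }

  R1 <- th1
  k2 <- th2 + th1 * k2a_hat
  # theta2 = 0 means the target is proportional to the reference: k2a (hence
  # k2) is unidentifiable, but R1 = theta1 and BP_ND = theta1 - 1 still are.
  BP <- if (degenerate) th1 - 1 else k2 / k2a_hat - 1
  params <- structure(list(R1 = R1, k2 = k2, BP_ND = BP,
                           k2a = k2a_hat, DVR = BP + 1),
                      class = "srtm_params")
  new_srtm_fit(params, wrss = wrss, weights = w, k2a = k2a_hat,
               boundary = boundary, degenerate = degenerate,
               target = target, ref = ref, grid = grid)
}

new_srtm_fit <- function(params, wrss, weights, k2a, boundary, degenerate,
                         target, ref, grid, method = "basis") {
  structure(list(params = params, wrss = wrss, weights = weights,
                 k2a = k2a, boundary = boundary, degenerate = degenerate,
                 target = target, ref = ref, grid = grid, method = method),
            class = "srtm_fit")
}

#' Direct nonlinear least-squares SRTM fit
#'
#' Brute-force reference fitter: weighted nonlinear least squares on
#' `(R1, k2, log k2a)` by Nelder-Mead from a multi-start lattice of
#' initial values.  Used as an independent cross-check of [fit_srtm]; slower
#' and with no grid, but the same forward model.
#'
#' @inheritParams fit_srtm
#' @param starts data frame of starting values (columns `R1`, `k2`, `k2a`);
#'   default a coarse lattice spanning plausible kinetics.
#' @return an `"srtm_fit"` with `method = "nls"`.  Non-convergence from all
#'   starts is an error, never a silent result.
#' @export
fit_srtm_nls <- function(target, ref, weights = NULL, starts = NULL) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  weights <- weights %||% default_weights(target$schedule)
  w <- weights
  w[target$schedule$start < 0] <- 0
  y <- target$values
  r <- ref$values
  knots <- pl_knots_from_tac(ref)
  sched <- target$schedule
  if (is.null(starts))
    starts <- expand.grid(R1 = 1, k2 = c(0.05, 0.15),
                          k2a = c(0.02, 0.08, 0.3))
  obj <- function(p) {
    k2a <- exp(p[3])
    b <- drop(conv_exp_frame_avg(knots, k2a, sched))
    model <- p[1] * r + (p[2] - p[1] * k2a) * b
    sum(w * (y - model)^2)
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$R1[s], starts$k2[s], log(starts$k2a[s])), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("NLS fit failed to converge from every start")
  R1 <- best$par[1]; k2 <- best$par[2]; k2a <- exp(best$par[3])
  params <- structure(list(R1 = R1, k2 = k2, BP_ND = k2 / k2a - 1,
                           k2a = k2a, DVR = k2 / k2a),
                      class = "srtm_params")
  new_srtm_fit(params, wrss = best$value, weights = w, k2a = k2a,
               boundary = FALSE, degenerate = FALSE,
               target = target, ref = ref, grid = NULL, method = "nls")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat("SRTM fit (", x$method, " method)\n", sep = "")
  print(x$params)
  cat(sprintf("  wrss = %.4g over %d weighted frames", x$wrss,
              sum(x$weights > 0)))
  if (x$boundary) cat("  [k2a at grid boundary]")
  if (x$degenerate) cat("  [degenerate: k2 unidentifiable]")
  cat("\n")
  invisible(x)
}

#' @export
coef.srtm_fit <- function(object, ...) {
  p <- object$params
  c(R1 = p$R1, k2 = p$k2, BP_ND = p$BP_ND, k2a = p$k2a, DVR = p$DVR)
}

#' @export
fitted.srtm_fit <- function(object, ...) {
  srtm_forward(object$params, object$ref)$values
}

#' @export
residuals.srtm_fit <- function(object, ...) {
  object$target$values - fitted(object)
}

#' Predict method for SRTM fits
#'
#' Evaluates the fitted model on a new frame schedule (using the stored
#' reference curve, which must cover the new schedule).
#'
#' @param object an `"srtm_fit"`.
#' @param schedule optional new [frame_schedule].
#' @param ... unused.
#' @export
predict.srtm_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) return(fitted(object))
  if (max(schedule$end) > max(object$ref$schedule$end) + 1e-9)
    stop("new schedule extends beyond the reference curve")
  knots <- pl_knots_from_tac(object$ref)
  p <- object$params
  rv <- pl_frame_avg(knots, schedule)
  cv <- drop(conv_exp_frame_avg(knots, p$k2a, schedule))
  rv * p$R1 + (p$k2 - p$R1 * p$k2a) * cv
}

#' @export
summary.srtm_fit <- function(object, ...) {
  w <- object$weights
  res <- residuals(object)
  out <- list(coef = coef(object), wrss = object$wrss,
              sigma = sqrt(object$wrss / max(1, sum(w > 0) - 3)),
              n_frames = sum(w > 0), boundary = object$boundary,
              degenerate = object$degenerate,
              max_abs_residual = max(abs(res[w > 0])))
  class(out) <- "summary.srtm_fit"
  out
}

#' @export
print.summary.srtm_fit <- function(x, ...) {
  cat("SRTM fit summary\n")
  print(round(x$coef, 5))
  cat(sprintf("  wrss %.4g, sigma %.4g, %d frames, max |resid| %.4g\n",
              x$wrss, x$sigma, x$n_frames, x$max_abs_residual))
  if (x$boundary) cat("  k2a on search boundary\n")
  if (x$degenerate) cat("  degenerate (k2 unidentifiable)\n")
  invisible(x)
}

#' @export
plot.srtm_fit <- function(x, ...) {
  sched <- x$target$schedule
  post <- sched$start >= 0
  t <- frame_midpoints(sched)[post]
  graphics::plot(t, x$target$values[post], pch = 16,
                 xlab = "time (min)", ylab = "concentration (kBq/mL)", ...)
  graphics::lines(t, fitted(x)[post], col = 2, lwd = 2)
  graphics::lines(t, x$ref$values[post], col = 4, lty = 2)
  graphics::legend("topright", c("target", "fit", "reference"),
                   col = c(1, 2, 4), pch = c(16, NA, NA),
                   lty = c(NA, 1, 2), bty = "n")
  invisible(x)
}
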