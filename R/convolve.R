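# Analytic convolution of a piecewise-linear curve with a decaying
# exponential.  This is the numerical core of the SRTM machinery: reference
# curves are represented as piecewise-linear functions of time (anchored at
# (0, 0)) and
#   y(t) = integral_0^t C(s) * exp(-lambda * (t - s)) ds
# is propagated segment-by-segment in closed form -- no quadrature grid, so
# irregular frame schedules (5 s to 10 min frames) introduce no resolution
# artefacts.  On a segment where C(s) = a + b s, with y(t0) known,
#   y(t)  = (a + b t)/lambda - b/lambda^2 + K exp(-lambda (t - t0)),
#   K     = y(t0) - (a + b t0)/lambda + b/lambda^2,
# and the integral of y over the segment is likewise closed-form.

# Piecewise-linear knots for a measured TAC: (0, 0) then (frame midpoint,
# value) for post-injection frames, linearly extrapolated to the last frame
# end so the curve is defined on the whole acquisition window.
pl_knots_from_tac <- function(x) {
  stopifnot(inherits(x, "tac"))
  post <- x$schedule$start >= 0
  mid <- frame_midpoints(x$schedule)[post]
  val <- x$values[post]
  t_end <- max(x$schedule$end)
  kt <- c(0, mid)
  kv <- c(0, val)
  n <- length(kt)
  if (kt[n] < t_end) {
    slope <- if (n >= 2) (kv[n] - kv[n - 1]) / (kt[n] - kt[n - 1]) else 0
    kt <- c(kt, t_end)
    kv <- c(kv, kv[n] + slope * (t_end - kt[n]))
  }
  list(t = kt, v = kv)
}

# Piecewise-linear knots sampling a continuous function on [0, t_end];
# breakpoints (e.g. frame boundaries) are honoured exactly.
pl_knots_from_fun <- function(f, t_end, breaks = numeric(0), n_grid = 1024) {
  kt <- sort(unique(c(seq(0, t_end, length.out = n_grid),
                      breaks[breaks >= 0 & breaks <= t_end])))
  list(t = kt, v = f(kt))
}

pl_interp <- function(knots, t) {
  v <- stats::approx(knots$t, knots$v, xout = t, rule = 2)$y
  v[t < knots$t[1]] <- 0
  v
}

# Exact average of the piecewise-linear curve over each frame (trapezoid on
# the merged breakpoints); frames before injection average to 0.
pl_frame_avg <- function(knots, sched) {
  t_end <- max(sched$end)
  bp <- sort(unique(c(knots$t, pmax(c(sched$start, sched$end), 0))))
  bp <- bp[bp >= 0 & bp <= t_end]
  v <- pl_interp(knots, bp)
  nseg <- length(bp) - 1
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  seg_int <- diff(bp) * (v[-1] + v[-length(v)]) / 2
  fidx <- findInterval(mid, sched$start)
  keep <- fidx >= 1 & fidx <= nrow(sched) & mid <= sched$end[fidx]
  out <- rep(0, nrow(sched))
  agg <- tapply(seg_int[keep], fidx[keep], sum)
  out[as.integer(names(agg))] <- agg
  out / frame_durations(sched)
  }

# Frame-averaged exponential convolution, vectorised over lambda.
# Returns a length(lambda) x nrow(sched) matrix.
conv_exp_frame_avg <- function(knots, lambda, sched) {
  t_end <- max(sched$end)
  bp <- sort(unique(c(knots$t, pmax(c(sched$start, sched$end), 0))))
  bp <- bp[bp >= 0 & bp <= t_end]
  v <- pl_interp(knots, bp)
  nseg <- length(bp) - 1
  nl <- length(lambda)
  il <- 1 / lambda
  il2 <- il * il
  y <- numeric(nl)                     # y at segment start; y(0) = 0
  fint <- matrix(0, nl, nrow(sched))   # accumulated integral per frame
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  fidx <- findInterval(mid, sched$start)
  ok <- fidx >= 1 & fidx <= nrow(sched) & mid <= sched$end[fidx]
  for (i in seq_len(nseg)) {
    h <- bp[i + 1] - bp[i]
    v0 <- v[i]; v1 <- v[i + 1]
    b <- (v1 - v0) / h
    K <- y - v0 * il + b * il2
    E <- exp(-lambda * h)
    seg <- (h * (v0 + v1) / 2) * il - b * h * il2 + K * (1 - E) * il
    y <- v1 * il - b * il2 + K * E
    if (ok[i]) fint[, fidx[i]] <- fint[, fidx[i]] + seg
  }
  fint * rep(1 / frame_durations(sched), each = nl)
}

# Pointwise exponential convolution at arbitrary times (scalar lambda).
conv_exp_at <- function(knots, lambda, times) {
  stopifnot(length(lambda) == 1)
  t_end <- max(knots$t)
  if (any(times > t_end + 1e-9))
    stop("requested time beyond the reference curve's support")
  bp <- sort(unique(c(knots$t, times[times >= 0])))
  v <- pl_interp(knots, bp)
  yv <- numeric(length(bp))            # y at every breakpoint; y(0) = 0
  for (i in seq_len(length(bp) - 1)) {
    h <- bp[i + 1] - bp[i]
    b <- (v[i + 1] - v[i]) / h
    K <- yv[i] - v[i] / lambda + b / lambda^2
    yv[i + 1] <- v[i + 1] / lambda - b / lambda^2 + K * exp(-lambda * h)
  }
  out <- numeric(length(times))
  pos <- times >= 0
  out[pos] <- yv[match(times[pos], bp)]
  out
}
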