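test_that("segment-analytic convolution matches brute-force quadrature", {
  set.seed(11)
  knots <- list(t = c(0, 0.5, 2, 5, 12, 30, 60),
                v = c(0, 40, 55, 30, 18, 9, 4))
  for (lam in c(0.01, 0.08, 0.5)) {
    t_eval <- c(0.7, 3, 10, 45, 60)
    expect_equal(conv_exp_at(knots, lam, t_eval),
                 conv_oracle(knots, lam, t_eval),
                 tolerance = 1e-5)
  }
})

test_that("frame-averaged convolution agrees with pointwise integration", {
  sch <- tiny_schedule()
  ref <- ref_fixture(sch, amp = 30)
  knots <- pl_knots_from_tac(ref)
  lam <- 0.12
  avg <- drop(conv_exp_frame_avg(knots, lam, sch))
  # independent check: trapezoid quadrature of dense pointwise values
  for (j in c(2, 5, 9)) {
    tt <- seq(sch$start[j], sch$end[j], length.out = 2001)
    y <- conv_exp_at(knots, lam, tt)
    trap <- sum((y[-1] + y[-length(y)]) / 2) * diff(tt[1:2]) /
      (sch$end[j] - sch$start[j])
    expect_equal(avg[j], trap, tolerance = 1e-6)
  }
})

test_that("bi-exponential reference has the closed-form peak and scales linearly", {
  t_peak <- log(0.5 / 0.05) / (0.5 - 0.05)        # ~5.117 min
  # on fine uniform frames the maximum frame average brackets the peak
  fine <- frame_schedule(48, 15, units = "s")      # 0.25-min frames, 0-12 min
  rf <- simulate_reference_tac(fine, amp = 50, lam1 = 0.05, lam2 = 0.5)
  jf <- which.max(rf$values)
  expect_true(fine$start[jf] <= t_peak && t_peak <= fine$end[jf])
  # on the coarse clinical schedule the winning frame abuts the peak time:
  # the wide 5-10 min frame averages below the adjacent 4-5 min frame
  sch <- manchester_schedule()
  ref <- simulate_reference_tac(sch, amp = 50, lam1 = 0.05, lam2 = 0.5)
  j <- which.max(ref$values)
  expect_lt(abs(t_peak - max(sch$start[j], min(sch$end[j], t_peak))), 0.2)
  expect_equal(ref$values[1], 0)                   # pre-injection frame
  ref2 <- simulate_reference_tac(sch, amp = 100, lam1 = 0.05, lam2 = 0.5)
  expect_equal(ref2$values, 2 * ref$values)
  expect_error(simulate_reference_tac(sch, amp = 1, lam1 = 0.5, lam2 = 0.1),
               "surge")
})

test_that("frame-averaged reference values equal the analytic integral", {
  sch <- frame_schedule(c(2, 2), c(1, 5), units = "min")
  amp <- 20; l1 <- 0.06; l2 <- 0.4
  ref <- simulate_reference_tac(sch, amp, l1, l2)
  f <- function(t) amp * (exp(-l1 * t) - exp(-l2 * t))
  for (j in seq_len(nrow(sch))) {
    v <- stats::integrate(f, sch$start[j], sch$end[j])$value /
      (sch$end[j] - sch$start[j])
    expect_equal(ref$values[j], v, tolerance = 1e-9)
  }
})
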