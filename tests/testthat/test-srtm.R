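test_that("step-input SRTM solution matches the closed form and plateaus at DVR", {
  p <- srtm_params(1.2, 0.1, 0.2)
  step <- function(t) as.numeric(t >= 0)
  tt <- c(0.25, 1, 2, 5, 10, 20, 40, 60)
  closed <- p$R1 + (p$k2 - p$R1 * p$k2a) * (1 - exp(-p$k2a * tt)) / p$k2a
  got <- srtm_curve(p, step, tt)
  expect_equal(got, closed, tolerance = 1e-10)
  expect_equal(srtm_curve(p, step, 400)[1], p$DVR, tolerance = 1e-8)
})

test_that("forward model honours the SRTM identity and linearity cases", {
  ref <- ref_fixture()
  # R1 = 1, BP = 0 gives k2 - R1 k2a = 0: output is the reference exactly
  ident <- srtm_forward(srtm_params(1, 0.1, 0), ref)
  expect_equal(ident$values, ref$values)
  # zero reference in, zero out
  z <- tac(ref$schedule, rep(0, nrow(ref$schedule)))
  expect_equal(srtm_forward(srtm_params(1.1, 0.1, 0.3), z)$values,
               z$values)
  expect_error(srtm_params(1, 0.1, -1.2), "BP_ND")
})

test_that("basis fitter recovers noiseless truth and flags boundaries", {
  ref <- ref_fixture()
  p <- srtm_params(1.05, 0.12, 0.25)
  fit <- fit_srtm(srtm_forward(p, ref), ref)
  expect_equal(coef(fit)[["R1"]], p$R1, tolerance = 1e-3)
  expect_equal(coef(fit)[["k2"]], p$k2, tolerance = 1e-3)
  expect_equal(coef(fit)[["BP_ND"]], p$BP_ND, tolerance = 1e-3)
  expect_false(fit$boundary)
  expect_false(fit$degenerate)
  # DVR = BP_ND + 1 identity holds for every fit
  expect_identical(coef(fit)[["DVR"]], coef(fit)[["BP_ND"]] + 1)
})

test_that("proportional and all-zero targets are flagged degenerate", {
  ref <- ref_fixture()
  # target = c * ref: R1 and BP_ND identifiable, k2 not
  prop <- tac(ref$schedule, 1.3 * ref$values)
  fit <- fit_srtm(prop, ref)
  expect_true(fit$degenerate)
  expect_equal(coef(fit)[["R1"]], 1.3, tolerance = 1e-10)
  expect_equal(coef(fit)[["BP_ND"]], 0.3, tolerance = 1e-10)
  # identity case
  fid <- fit_srtm(ref, ref)
  expect_true(fid$degenerate)
  expect_equal(coef(fid)[["R1"]], 1, tolerance = 1e-10)
  expect_equal(coef(fid)[["BP_ND"]], 0, tolerance = 1e-10)
  # the spec of the forward model makes (R1 = 1.2, k2 = R1 * k2a) degenerate
  pd <- srtm_params(1.2, 0.1, 0.2)   # k2 - R1 k2a = 0 exactly
  fd <- fit_srtm(srtm_forward(pd, ref), ref)
  expect_true(fd$degenerate)
  expect_equal(coef(fd)[["BP_ND"]], 0.2, tolerance = 1e-10)
  # all-zero target
  fz <- fit_srtm(tac(ref$schedule, rep(0, nrow(ref$schedule))), ref)
  expect_true(fz$degenerate)
  expect_equal(coef(fz)[["R1"]], 0)
  expect_equal(coef(fz)[["BP_ND"]], 0)
})

test_that("fits are scale equivariant", {
  ref <- ref_fixture()
  p <- srtm_params(0.9, 0.08, 0.4)
  target <- srtm_forward(p, ref)
  base <- coef(fit_srtm(target, ref))
  # both scaled: parameters unchanged
  both <- coef(fit_srtm(tac(ref$schedule, 3 * target$values),
                        tac(ref$schedule, 3 * ref$values)))
  expect_equal(both[c("R1", "k2", "BP_ND")], base[c("R1", "k2", "BP_ND")],
               tolerance = 1e-6)
  # target only scaled: R1 and k2 scale, k2a (model shape) consistent
  tonly <- coef(fit_srtm(tac(ref$schedule, 3 * target$values), ref))
  expect_equal(tonly[["R1"]], 3 * base[["R1"]], tolerance = 1e-6)
  expect_equal(tonly[["k2"]], 3 * base[["k2"]], tolerance = 1e-6)
  expect_equal(tonly[["k2a"]], base[["k2a"]], tolerance = 1e-4)
})

test_that("basis fitter agrees with the NLS oracle on noiseless truths", {
  ref <- ref_fixture()
  B <- srtm_basis(ref)
  set.seed(202)
  for (i in 1:12) {
    p <- srtm_params(runif(1, 0.7, 1.4), runif(1, 0.03, 0.3),
                     runif(1, -0.2, 1.0))
    target <- srtm_forward(p, ref)
    fb <- fit_srtm(target, ref, basis = B)
    fn <- fit_srtm_nls(target, ref)
    expect_lt(abs(coef(fb)[["BP_ND"]] - coef(fn)[["BP_ND"]]), 1e-3)
    expect_lt(abs(coef(fb)[["R1"]] - coef(fn)[["R1"]]), 1e-3)
    # zero-residual property of the oracle on noiseless data
    expect_lt(fn$wrss, 1e-12 * sum(target$values^2))
  }
})

test_that("fit rejects mismatched schedules and too few frames", {
  ref <- ref_fixture()
  other <- ref_fixture(turku_schedule())
  expect_error(fit_srtm(other, ref), "schedule")
  sch2 <- frame_schedule(2, 1, units = "min")
  expect_error(fit_srtm(tac(sch2, c(1, 2)), tac(sch2, c(1, 2))),
               "at least 3")
})

test_that("srtm_fit methods are coherent", {
  ref <- ref_fixture()
  p <- srtm_params(1.1, 0.09, 0.3)
  target <- add_tac_noise(srtm_forward(p, ref), 0.2, seed = 5)
  fit <- fit_srtm(target, ref)
  expect_equal(fitted(fit) + residuals(fit), target$values)
  expect_equal(predict(fit), fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.srtm_fit")
  expect_equal(sum(fit$weights * residuals(fit)^2), fit$wrss,
               tolerance = 1e-8)
  expect_output(print(fit), "SRTM fit")
})
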