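test_that("cohort generation matches configured counts and is deterministic", {
  cfg <- cohort_config(seed = 13)
  a <- generate_cohort(cfg)
  expect_equal(nrow(a$subjects), 76)
  expect_equal(sum(a$subjects$centre == "Manchester"), 50)
  expect_equal(sum(a$subjects$centre == "Turku"), 26)
  expect_equal(as.integer(table(a$subjects$handedness)[c("right", "left", "unknown")]),
               c(59L, 8L, 9L))
  b <- generate_cohort(cohort_config(seed = 13))
  expect_identical(a, b)
  # DVR = BP_ND + 1 exactly in the truth table
  expect_identical(a$truth$params$DVR, a$truth$params$BP_ND + 1)
})

test_that("cohorts are extensible without reshuffling earlier subjects", {
  a <- generate_cohort(cohort_config(n_per_centre = c(Manchester = 5, Turku = 3),
                                     seed = 9))
  b <- generate_cohort(cohort_config(n_per_centre = c(Manchester = 5, Turku = 6),
                                     seed = 9))
  expect_equal(a$subjects$age, b$subjects$age[1:8])
  expect_equal(a$truth$intercept, b$truth$intercept[1:8])
})

test_that("null asymmetry with zero pair noise gives exactly equal sides", {
  c0 <- generate_cohort(cohort_config(asym_rel_diff_pct = 0, pair_sd = 0,
                                      seed = 2))
  p <- c0$truth$params
  l <- p[p$side == "left", ]; r <- p[p$side == "right", ]
  expect_identical(l$DVR, r$DVR)
})

test_that("null calibration: mean right-minus-left truth is centred on zero", {
  diffs <- unlist(lapply(1:25, function(s) {
    p <- generate_cohort(cohort_config(asym_rel_diff_pct = 0,
                                       seed = s))$truth$params
    p <- p[p$region == "grey_matter", ]
    mean(p$DVR[p$side == "right"] - p$DVR[p$side == "left"])
  }))
  pair_sd <- cohort_config()$pair_sd[["grey_matter"]]
  se <- pair_sd / sqrt(76 * 25)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("injected relative difference is recovered in expectation on truth", {
  cfg <- cohort_config()
  rel <- sapply(1:20, function(s) {
    p <- generate_cohort(cohort_config(seed = s))$truth$params
    p <- p[p$region == "putamen", ]
    l <- p$DVR[p$side == "left"]; r <- p$DVR[p$side == "right"]
    100 * mean(r - l) / mean(c(mean(l), mean(r)))
  })
  se <- sd(rel) / sqrt(length(rel))
  expect_lt(abs(mean(rel) - cfg$asym_rel_diff_pct[["putamen"]]), 3 * se)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_per_centre = c(Manchester = -1, Turku = 5)),
               "non-negative")
  expect_error(cohort_config(n_per_centre = c(Manchester = 0, Turku = 0)),
               "empty cohort")
  expect_error(cohort_config(baseline_dvr = c(thalamus = -1)), "positive")
  expect_error(cohort_config(asym_rel_diff_pct = 250), "below 200")
  expect_error(cohort_config(sex_prop = c(male = 0.7, female = 0.7)),
               "sum to 1")
  expect_error(cohort_config(pair_sd = -0.1), "non-negative")
})

test_that("frame-variance noise has the stated sigma and zero-noise identity", {
  sch <- frame_schedule(1, 5, units = "min")
  x <- tac(sch, 10)
  expect_identical(add_tac_noise(x, 0, seed = 1), x)
  expect_identical(add_tac_noise(x, 1, seed = 4)$values,
                   add_tac_noise(x, 1, seed = 4)$values)
  draws <- vapply(1:10000, function(s) add_tac_noise(x, 1, seed = s)$values,
                  numeric(1))
  # sigma = alpha * sqrt(value / duration) = sqrt(10/5)
  expect_equal(sd(draws - 10), sqrt(2), tolerance = 0.02)
  expect_error(add_tac_noise(x, -1, seed = 1), "non-negative")
})

test_that("subject TAC simulation honours identity and errors on missing regions", {
  cfg <- cohort_config(n_per_centre = c(Manchester = 2, Turku = 1), seed = 3)
  cohort <- generate_cohort(cfg)
  sch <- manchester_schedule()
  ref <- ref_fixture(sch)
  tacs <- simulate_subject_tacs("S001", cohort$truth, sch, ref)
  expect_named(tacs, c(paste(rep(cfg$regions, each = 2),
                             c("left", "right"), sep = "."),
                       "cerebellum_gm.bilateral"), ignore.order = TRUE)
  expect_identical(tacs[["cerebellum_gm.bilateral"]], ref)
  expect_error(simulate_subject_tacs("S001", cohort$truth, sch, ref,
                                     regions = "amygdala"), "amygdala")
  expect_error(simulate_subject_tacs("nobody", cohort$truth, sch, ref),
               "no truth rows")
  # identity parameters reproduce the reference frame-for-frame
  tr <- cohort$truth
  tr$params[tr$params$subject_id == "S001", c("R1", "k2", "BP_ND", "DVR")] <-
    data.frame(R1 = 1, k2 = 0.1, BP_ND = 0, DVR = 1)
  tacs2 <- simulate_subject_tacs("S001", tr, sch, ref, regions = "thalamus")
  expect_equal(tacs2[["thalamus.left"]]$values, ref$values)
})
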