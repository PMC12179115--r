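test_that("asymmetry index and relative difference identities hold", {
  expect_equal(asymmetry_index(1, 1), 0)
  expect_equal(asymmetry_index(0.9, 1.1), 0.1)
  # printed-median spot checks
  expect_equal(asymmetry_index(1.15, 1.21), 0.06 / 2.36)
  expect_equal(relative_difference(1.08, 1.11), 100 * 0.03 / 1.095)
  expect_equal(relative_difference(1.1, 0.9), -20)
  set.seed(77)
  for (i in 1:200) {
    l <- runif(1, 0.1, 3); r <- runif(1, 0.1, 3)
    ai <- asymmetry_index(l, r)
    expect_equal(ai, -asymmetry_index(r, l))
    expect_true(ai > -1 && ai < 1)
    expect_equal(relative_difference(l, r), 200 * ai)
  }
  expect_error(asymmetry_index(-2, 1), "positive")
  expect_error(relative_difference(0, 0), "positive")
})

test_that("paired Cohen's d matches hand computation and its equivariances", {
  expect_equal(paired_cohens_d(c(0, 0, 0), c(1, 2, 3)), 2)  # mean 2, sd 1
  set.seed(31)
  l <- rnorm(20, 1, 0.1); r <- rnorm(20, 1.05, 0.1)
  d <- paired_cohens_d(l, r)
  expect_equal(paired_cohens_d(r, l), -d)            # side swap: sign flip
  expect_equal(paired_cohens_d(l + 5, r + 5), d)     # common shift invariant
  expect_error(paired_cohens_d(1:3, 1:3 + 2), "zero standard deviation")
  expect_error(paired_cohens_d(1, 2), "at least 2")
})

test_that("percent above reference is the documented helper formula", {
  expect_equal(percent_above_reference(1.08, 1.11, 1.10),
               100 * 0.03 / 1.10)
  expect_error(percent_above_reference(1, 2, 0), "positive")
})

test_that("per-region summary matches hand computation on a toy table", {
  paired <- data.frame(subject_id = rep(c("a", "b"), 2),
                       region = rep(c("thalamus", "putamen"), each = 2),
                       DVR_left = c(1.0, 1.2, 0.9, 1.1),
                       DVR_right = c(1.1, 1.4, 1.0, 1.0))
  s <- summarize_asymmetry(paired, tests = FALSE)
  th <- s[s$region == "thalamus", ]
  expect_equal(th$median_left, 1.1)
  expect_equal(th$q25_left, 1.05)      # type-7 linear interpolation
  expect_equal(th$q75_right, 1.325)
  # rel diff: mean diff 0.15 over mean of side means (1.1, 1.25) -> 1.175
  expect_equal(th$rel_diff_pct, 100 * 0.15 / 1.175)
  expect_equal(th$mean_ai,
               mean(c(0.1 / 2.1, 0.2 / 2.6)))
  pu <- s[s$region == "putamen", ]
  expect_equal(pu$cohens_d, mean(c(0.1, -0.1)) / sd(c(0.1, -0.1)))
})

test_that("summary flags degenerate and incomplete tables", {
  same <- data.frame(subject_id = c("a", "b", "c"), region = "gm",
                     DVR_left = c(1, 1.1, 1.2), DVR_right = c(1, 1.1, 1.2))
  s <- summarize_asymmetry(same, tests = FALSE)
  expect_equal(s$mean_ai, 0)
  expect_true(is.na(s$cohens_d))      # zero-SD differences
  bad <- data.frame(subject_id = c("a", "b"), region = "gm",
                    DVR_left = c(1, NA), DVR_right = c(1.1, 1.2))
  expect_error(summarize_asymmetry(bad), "b")
  one <- data.frame(subject_id = "a", region = "gm",
                    DVR_left = 1, DVR_right = 1.1)
  expect_error(summarize_asymmetry(one), "2 subjects")
})

test_that("DVR- and BP-based orderings agree (affine shift by one)", {
  set.seed(5)
  dvr_l <- runif(30, 1.0, 1.3); dvr_r <- runif(30, 1.0, 1.3)
  expect_identical(dvr_r > dvr_l, (dvr_r - 1) > (dvr_l - 1))
})
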