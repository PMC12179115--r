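test_that("exact signed-rank p-values equal brute-force enumeration", {
  # spec'd hand case: differences (1, 2, 3) -> W+ = 6, p = 2/8
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_raw, 0.25)
  expect_true(res$exact)
  set.seed(41)
  for (n in 3:8) {
    for (rep in 1:5) {
      d <- round(runif(n, -1, 1), 3)
      d <- d[d != 0]
      if (length(d) < 3 || any(duplicated(abs(d)))) next
      got <- wilcoxon_signed_rank(d, rep(0, length(d)))
      expect_true(got$exact)
      expect_equal(got$p_raw, wilcoxon_enum_p(d))
    }
  }
})

test_that("signed-rank handles degenerate and swapped inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_signed_rank(x, x)$p_raw, 1)
  expect_true(wilcoxon_signed_rank(x, x)$degenerate)
  y <- c(0.5, 2.5, 2, 5)
  a <- wilcoxon_signed_rank(x, y); b <- wilcoxon_signed_rank(y, x)
  expect_equal(a$p_raw, b$p_raw)
  n <- a$n
  expect_equal(a$statistic, n * (n + 1) / 2 - b$statistic)  # reflected
})

test_that("large-sample signed-rank path tracks the base-R implementation", {
  set.seed(99)
  x <- rnorm(76, 0.02, 0.05)
  got <- wilcoxon_signed_rank(x, rep(0, 76))
  expect_false(got$exact)
  ref <- stats::wilcox.test(x, exact = FALSE, correct = TRUE)
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("exact Mann-Whitney p-values equal labeling enumeration", {
  res <- mann_whitney_u(1:3, 4:6)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 0.1)              # 2/20
  expect_true(res$exact)
  set.seed(17)
  for (rep in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2), 3)
    if (any(duplicated(c(x, y)))) next
    got <- mann_whitney_u(x, y)
    expect_true(got$exact)
    expect_equal(got$p_raw, mann_whitney_enum_p(x, y))
  }
})

test_that("Mann-Whitney invariances and degenerate cases", {
  x <- c(1, 2, 3, 4.5); y <- c(2.5, 3.5, 6)
  a <- mann_whitney_u(x, y)
  expect_equal(mann_whitney_u(x + 10, y + 10)$p_raw, a$p_raw)  # shift
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)           # n1 n2 / 2
  expect_equal(same$p_raw, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Holm-Sidak step-down matches its closed forms", {
  expect_equal(holm_sidak_adjust(0.03), 0.03)                 # m = 1
  p0 <- 0.02
  expect_equal(holm_sidak_adjust(rep(p0, 4)), rep(1 - (1 - p0)^4, 4))
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone when sorted
  }
  expect_error(holm_sidak_adjust(c(0.2, 1.3)), "0, 1")
})

test_that("Shapiro-Wilk wrapper enforces its contract and has power", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(1:2), "3 <= n")
  normal_ok <- vapply(1:40, function(s) {
    with_seed(s, shapiro_wilk(rnorm(76))$statistic > 0.95)
  }, logical(1))
  expect_gte(mean(normal_ok), 0.9)
  expo_rej <- vapply(1:40, function(s) {
    with_seed(s, shapiro_wilk(rexp(76))$p_raw < 0.05)
  }, logical(1))
  expect_gte(mean(expo_rej), 0.9)
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10))$statistic, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2))$statistic, 0.5)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("balanced hemisphere-only LME reduces to the mean paired difference", {
  set.seed(3)
  n <- 24
  l <- rnorm(n, 1.07, 0.05); r <- l + rnorm(n, 0.02, 0.01)
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), 2),
                  hemisphere = rep(c("left", "right"), each = n),
                  DVR = c(l, r))
  fit <- fit_lme_random_intercept(d, covariates = character(0))
  expect_equal(unname(coef(fit)["hemisphereright"]), mean(r - l),
               tolerance = 1e-10)
})

test_that("the full fixed-effect battery fits and excludes unknown handedness", {
  q <- generate_cohort(cohort_config(seed = 21))
  p <- q$truth$params[q$truth$params$region == "brain_gmwm", ]
  d <- merge(p, q$subjects, by = "subject_id")
  names(d)[names(d) == "side"] <- "hemisphere"
  fit <- fit_lme_random_intercept(d)
  expect_equal(fit$n_excluded, 9)
  expect_equal(fit$n_subjects, 67)
  expect_equal(fit$n_rows, 134)
  terms <- fit$fixed$term
  expect_true(all(c("hemisphereright", "age", "sexmale", "handednessright",
                    "centreTurku", "hemisphereright:centreTurku") %in% terms))
  h <- fit$fixed[fit$fixed$term == "hemisphereright", ]
  expect_true(h$ci_lo <= h$estimate && h$estimate <= h$ci_hi)
  expect_true(all(fit$varcomp >= 0))
  # singular design: one centre with an interaction requested
  d1 <- d[d$centre == "Manchester", ]
  expect_error(fit_lme_random_intercept(d1), "centre")
})
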