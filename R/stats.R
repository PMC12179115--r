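#' @title Nonparametric tests and multiplicity correction
#' @description
#' In-package implementations of the paired Wilcoxon signed-rank test and
#' the Mann-Whitney U test with exact small-sample null distributions
#' (dynamic-programming enumeration), switching to tie-corrected,
#' continuity-corrected normal approximations for larger samples or ties,
#' plus the Holm-Sidak step-down multiplicity adjustment.  The exact paths
#' are implemented here (rather than delegated) so they can be verified
#' against brute-force enumeration.
#' @name nonparametrics
NULL

new_test_result <- function(method, statistic, p, n, exact,
                            degenerate = FALSE, extra = list()) {
  structure(c(list(method = method, statistic = statistic, p_raw = p,
                   p_adjusted = NA_real_, n = n, exact = exact,
                   degenerate = degenerate), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p_raw), if (x$exact) " (exact)" else " (approximate)",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  if (!is.na(x$p_adjusted))
    cat("  adjusted p = ", format.pval(x$p_adjusted), "\n", sep = "")
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W+ for n untied
# ranks: counts of subset sums of {1..n} by polynomial convolution.
signrank_counts <- function(n) {
  f <- c(1, numeric(n * (n + 1) / 2))
  for (r in seq_len(n)) {
    g <- c(numeric(r), f[seq_len(length(f) - r)])
    f <- f + g
  }
  f  # counts for W+ = 0 .. n(n+1)/2, total 2^n
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test of `x` against `y`.  Zero differences are dropped
#' (the classical convention).  With at most 25 non-zero differences and no
#' tied absolute differences the p-value is exact (full enumeration of the
#' 2^n sign assignments via subset-sum counting); otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact_max largest n for which the exact path is used.
#' @return a `"test_result"` with the W+ statistic.  If every difference is
#'   zero the result is degenerate with p = 1.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))$p_raw  # exact 2/8
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired")
  d <- x - y
  d <- d[!is.na(d)]
  keep <- d != 0
  n_zero <- sum(!keep)
  d <- d[keep]
  n <- length(d)
  if (n == 0)
    return(new_test_result("Wilcoxon matched-pairs signed rank", 0, 1, 0,
                           exact = TRUE, degenerate = TRUE))
  if (n < 3)
    return(new_test_result("Wilcoxon matched-pairs signed rank",
                           sum(rank(abs(d))[d > 0]), 1, n,
                           exact = TRUE, degenerate = TRUE,
                           extra = list(note = "fewer than 3 non-zero differences")))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    counts <- signrank_counts(n)
    tot <- 2^n
    p_le <- sum(counts[seq_len(W + 1)]) / tot          # P(W+ <= W)
    p_ge <- sum(counts[seq(W + 1, length(counts))]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_test_result("Wilcoxon matched-pairs signed rank", W, p, n,
                           exact = TRUE, extra = list(n_zero = n_zero)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  new_test_result("Wilcoxon matched-pairs signed rank", W, min(1, p), n,
                  exact = FALSE, extra = list(n_zero = n_zero, z = z))
}

# Counts of the Mann-Whitney U null distribution (partitions of u into at
# most m parts each <= n), by the recurrence
#   N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
mannwhitney_counts <- function(m, n) {
  umax <- m * n
  prev <- vector("list", m + 1)           # N(.; j, 0)
  for (j in 0:m) prev[[j + 1]] <- c(1, numeric(umax))
  for (nn in seq_len(n)) {
    cur <- vector("list", m + 1)
    cur[[1]] <- c(1, numeric(umax))
    for (j in seq_len(m)) {
      shifted <- c(numeric(nn), cur[[j]][seq_len(umax + 1 - nn)])
      cur[[j + 1]] <- shifted + prev[[j + 1]]
    }
    prev <- cur
  }
  prev[[m + 1]]  # counts for U = 0..umax, total choose(m + n, m)
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test.  With `min(n1, n2) <= 8` and no ties
#' across the pooled sample the p-value is exact (enumeration of all
#' `choose(n1 + n2, n1)` labelings via a partition-counting recurrence);
#' otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest `min(n1, n2)` for which the exact path is used.
#' @return a `"test_result"` with the U statistic of `x`.
#' @examples
#' mann_whitney_u(1:3, 4:6)$p_raw  # exact 2/20
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= exact_max && !ties) {
    counts <- mannwhitney_counts(n1, n2)
    tot <- choose(n1 + n2, n1)
    p_le <- sum(counts[seq_len(U + 1)]) / tot
    p_ge <- sum(counts[seq(U + 1, length(counts))]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_test_result("Mann-Whitney U", U, p, c(n1 = n1, n2 = n2),
                           exact = TRUE))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  new_test_result("Mann-Whitney U", U, min(1, p), c(n1 = n1, n2 = n2),
                  exact = FALSE, extra = list(z = z))
}

#' Shapiro-Wilk normality test
#'
#' Thin contract wrapper around [stats::shapiro.test] (the standard
#' published approximation of the W null distribution).
#'
#' @param x numeric vector, `3 <= length <= 5000`, not all equal.
#' @return a `"test_result"` with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant vector: normality test undefined")
  sw <- stats::shapiro.test(x)
  new_test_result("Shapiro-Wilk", unname(sw$statistic), sw$p.value,
                  length(x), exact = FALSE)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m raw p-values ascending, sets
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotone
#' non-decreasing adjusted values along the sorted order, caps at 1, and
#' returns them in the original order.  For m equal p-values this reduces to
#' the single-step Sidak correction `1 - (1 - p)^m`.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  pmin(adj, 1)[order(o)]
}

#' Pearson correlation test
#'
#' r and its two-sided p-value via the t transform with n - 2 degrees of
#' freedom (delegating to [stats::cor.test]).
#'
#' @param x,y numeric vectors of equal length `>= 3`, both non-constant.
#' @return a `"test_result"` with statistic r and field `t`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_result("Pearson correlation", unname(ct$estimate), ct$p.value,
                  length(x), exact = FALSE,
                  extra = list(t = unname(ct$statistic),
                               ci = unname(ct$conf.int)))
}
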