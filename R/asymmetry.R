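#' Laterality metrics
#'
#' `asymmetry_index()` computes `AI = (right - left)/(right + left)`:
#' dimensionless, positive when the right value is larger, bounded in
#' (-1, 1) for positive inputs.  `relative_difference()` computes the signed
#' percentage `100 * (right - left) / ((left + right)/2)`, which equals
#' `200 * AI` identically.  Both are vectorised.
#'
#' The relative difference is reported signed (its absolute value is the
#' literal "absolute difference over the mean"); the sign convention is
#' positive = right greater than left throughout the package.
#'
#' @param left,right paired values (e.g. DVR, R1, volume); `left + right`
#'   must be positive.
#' @return numeric vector.
#' @examples
#' asymmetry_index(0.9, 1.1)       # 0.1
#' relative_difference(1.15, 1.21) # +5.08% (thalamus-like medians)
#' @export
asymmetry_index <- function(left, right) {
  s <- left + right
  if (any(s <= 0)) stop("`left + right` must be positive")
  (right - left) / s
}

#' @rdname asymmetry_index
#' @export
relative_difference <- function(left, right) {
  m <- (left + right) / 2
  if (any(m <= 0)) stop("mean of `left` and `right` must be positive")
  100 * (right - left) / m
}

#' Paired Cohen's d
#'
#' Effect size of a paired difference: the mean of the paired differences
#' divided by their sample standard deviation (denominator `n - 1`).
#' Positive when right exceeds left on average.
#'
#' @param left,right paired vectors of equal length `>= 2`.
#' @return scalar d.
#' @examples
#' paired_cohens_d(c(0, 0, 0), c(1, 2, 3))  # mean 2 / sd 1 = 2
#' @export
paired_cohens_d <- function(left, right) {
  if (length(left) != length(right)) stop("`left` and `right` must be paired")
  if (length(left) < 2) stop("need at least 2 pairs")
  d <- right - left
  s <- stats::sd(d)
  if (s == 0) stop("degenerate: paired differences have zero standard deviation")
  mean(d) / s
}

#' Percent elevation above a reference value
#'
#' Helper expressing a right-minus-left difference as a percentage of a
#' bilateral reference value: `100 * (right - left) / reference`.  Related
#' to, but distinct from, [relative_difference] (which normalises by the
#' mean of the two sides).
#'
#' @param left,right paired values.
#' @param reference positive reference value.
#' @export
percent_above_reference <- function(left, right, reference) {
  if (any(reference <= 0)) stop("`reference` must be positive")
  100 * (right - left) / reference
}

#' Summarise hemispheric asymmetry per region
#'
#' For each region of a paired table the summary holds: per-side median and
#' IQR (quartiles by linear interpolation, `stats::quantile` type 7), the
#' cohort-level signed relative difference (mean paired difference over the
#' mean of the side means -- a cohort summary, not a function of the
#' medians), the per-subject asymmetry-index distribution, paired Cohen's d,
#' and the Shapiro-Wilk p-value of the right-minus-left differences.
#' Wilcoxon p-values (raw and Holm-Sidak adjusted across the regions of the
#' table) are attached when `tests = TRUE`.
#'
#' @param paired data frame with columns `subject_id`, `region`,
#'   `DVR_left`, `DVR_right` (one row per subject x region).
#' @param value base name of the paired columns (default `"DVR"`).
#' @param tests attach Wilcoxon signed-rank p-values with Holm-Sidak
#'   adjustment across regions.
#' @return data frame of class `"asymmetry_summary"`, one row per region,
#'   with an `ai` attribute holding the per-subject AI values (long form).
#' @export
summarize_asymmetry <- function(paired, value = "DVR", tests = TRUE) {
  lc <- paste0(value, "_left"); rc <- paste0(value, "_right")
  need <- c("subject_id", "region", lc, rc)
  miss <- setdiff(need, names(paired))
  if (length(miss)) stop("paired table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(paired[, c(lc, rc)])
  if (any(bad))
    stop("missing side value for subject ", paired$subject_id[bad][1],
         ", region ", paired$region[bad][1])
  if (length(unique(paired$subject_id)) < 2) stop("need at least 2 subjects")

  regions <- unique(paired$region)
  rows <- lapply(regions, function(rg) {
    d <- paired[paired$region == rg, ]
    l <- d[[lc]]; r <- d[[rc]]
    qs_l <- stats::quantile(l, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qs_r <- stats::quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    diffs <- r - l
    data.frame(region = rg, n = nrow(d),
               median_left = qs_l[2], q25_left = qs_l[1], q75_left = qs_l[3],
               median_right = qs_r[2], q25_right = qs_r[1], q75_right = qs_r[3],
               rel_diff_pct = 100 * mean(diffs) / mean(c(mean(l), mean(r))),
               mean_ai = mean(asymmetry_index(l, r)),
               cohens_d = if (stats::sd(diffs) > 0) mean(diffs) / stats::sd(diffs)
                          else NA_real_,
               shapiro_p = if (length(diffs) >= 3 && stats::sd(diffs) > 0)
                 stats::shapiro.test(diffs)$p.value else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (tests) {
    praw <- vapply(regions, function(rg) {
      d <- paired[paired$region == rg, ]
      wilcoxon_signed_rank(d[[rc]], d[[lc]])$p_raw
    }, numeric(1))
    out$p_wilcoxon <- praw
    out$p_adjusted <- holm_sidak_adjust(praw)
  }
  ai_long <- data.frame(subject_id = paired$subject_id,
                        region = paired$region,
                        ai = asymmetry_index(paired[[lc]], paired[[rc]]))
  attr(out, "ai") <- ai_long
  attr(out, "value") <- value
  class(out) <- c("asymmetry_summary", "data.frame")
  out
}

#' @export
print.asymmetry_summary <- function(x, digits = 4, ...) {
  cat("Hemispheric asymmetry summary (", attr(x, "value"),
      "; positive = right > left)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
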