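# Shared fixtures: a coarse test schedule, a canonical reference input, and
# a memoised grey-matter cohort sweep reused by the slower simulation tests.

tiny_schedule <- function() {
  frame_schedule(counts = c(4, 4, 2), durations = c(0.5, 2, 10),
                 units = "min")
}

ref_fixture <- function(schedule = manchester_schedule(), amp = 50) {
  simulate_reference_tac(schedule, amp = amp, lam1 = 0.05, lam2 = 0.5)
}

# Brute-force convolution oracle: fine-grid trapezoid quadrature of
# int_0^t C(s) exp(-lambda (t - s)) ds for a piecewise-linear C.
conv_oracle <- function(knots, lambda, t_eval, dt = 1e-3) {
  vapply(t_eval, function(tt) {
    if (tt <= 0) return(0)
    s <- seq(0, tt, by = dt)
    cs <- stats::approx(knots$t, knots$v, xout = s, rule = 2)$y
    cs[s < knots$t[1]] <- 0
    f <- cs * exp(-lambda * (tt - s))
    sum((f[-1] + f[-length(f)]) / 2) * dt
  }, numeric(1))
}

# Brute-force exact Wilcoxon signed-rank p: enumerate all 2^n sign patterns.
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_ge <- mean(Ws >= W)
  p_le <- mean(Ws <= W)
  min(1, 2 * min(p_ge, p_le))
}

# Brute-force exact Mann-Whitney p: enumerate all choose(n1+n2, n1) labelings.
mann_whitney_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  Us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# Memoised 200-seed grey-matter cohort sweep at the default configuration:
# per seed, the fitted GM/GMWM asymmetry summary and the fitted-vs-truth
# regional DVR bias.  Computed once per test run.
gm_sweep_env <- new.env()
gm_sweep <- function(n_seeds = 200) {
  key <- paste0("s", n_seeds)
  if (!is.null(gm_sweep_env[[key]])) return(gm_sweep_env[[key]])
  rows <- lapply(seq_len(n_seeds), function(s) {
    q <- quantify_cohort(cohort_config(seed = s),
                         regions = c("grey_matter", "brain_gmwm"))
    sm <- summarize_asymmetry(pair_measurements(q$measurements))
    m <- merge(q$measurements,
               q$cohort$truth$params[, c("subject_id", "region", "side", "DVR")],
               by = c("subject_id", "region", "side"),
               suffixes = c("", "_true"))
    bias <- tapply((m$DVR - m$DVR_true) / m$DVR_true, m$region, mean)
    gm <- sm[sm$region == "grey_matter", ]
    gmwm <- sm[sm$region == "brain_gmwm", ]
    data.frame(seed = s,
               gm_rel = gm$rel_diff_pct, gm_d = gm$cohens_d,
               gm_adj_p = gm$p_adjusted,
               gmwm_rel = gmwm$rel_diff_pct, gmwm_d = gmwm$cohens_d,
               bias_gm = unname(bias[["grey_matter"]]),
               bias_gmwm = unname(bias[["brain_gmwm"]]))
  })
  gm_sweep_env[[key]] <- do.call(rbind, rows)
  gm_sweep_env[[key]]
}
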