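#' Synthetic cohort configuration
#'
#' Describes a two-centre cohort of subjects with known ground-truth regional
#' SRTM parameters and a configurable right-minus-left binding asymmetry.
#' The defaults emulate the statistical structure of the reference study
#' conditions: 50 Manchester + 26 Turku subjects, six bilateral regions plus
#' hemispheric grey-matter (GM) and grey+white-matter (GMWM) aggregates, a
#' bilateral cerebellar grey-matter pseudoreference, rightward DVR asymmetry
#' of about +1.9% at the hemispheric level (paired Cohen's d near 1.1),
#' Gaussian right-minus-left differences, and null covariate effects.
#'
#' @param n_per_centre named integer vector, subjects per centre.
#' @param baseline_dvr named numeric vector, bilateral mean DVR per region.
#' @param asym_rel_diff_pct named numeric vector, injected signed relative
#'   difference per region (%; positive = right > left); recycled if scalar.
#' @param subject_sd SD of the per-subject global DVR intercept.
#' @param pair_sd SD of the within-subject right-minus-left DVR residual;
#'   scalar or named per region.
#' @param r1_mean,r1_sd tracer delivery ratio distribution.
#' @param k2_ref reference-region clearance (1/min); target `k2 = R1 * k2_ref`.
#' @param age_range,sex_prop,handedness_prop covariate distributions;
#'   proportions must sum to 1.  Handedness includes an `unknown` class.
#' @param activity_meanlog,activity_sdlog named per-centre lognormal
#'   parameters of injected activity (MBq).
#' @param weight_mean,weight_sd body weight distribution (kg).
#' @param vol_ml,vol_asym_pct,vol_cv bilateral region volumes (mL), their
#'   signed right-minus-left asymmetry (%), and per-side lognormal-free
#'   Gaussian CV.
#' @param suv_asym_pct signed right-minus-left scale difference applied to
#'   the left/right cerebellar TACs (%), driving the SUV asymmetry readout.
#' @param amp_scale,lam1,lam2 reference-input shape: peak scale per unit
#'   injected activity per kg, and the two rate constants of [biexp_input].
#' @param noise_alpha TAC noise scale passed to [add_tac_noise].
#' @param age_slope,sex_effect,hand_effect,centre_effect optional covariate
#'   effects on DVR (all 0 by default, matching the null findings emulated).
#' @param seed master RNG seed (integer).
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_centre = c(Manchester = 50, Turku = 26),
                          baseline_dvr = c(thalamus = 1.18, putamen = 1.09,
                                           temporal = 1.03, frontal = 1.09,
                                           occipital = 1.11, parietal = 1.11,
                                           grey_matter = 1.09,
                                           brain_gmwm = 1.09),
                          asym_rel_diff_pct = c(thalamus = 3.09,
                                                putamen = 3.55,
                                                temporal = 2.78,
                                                frontal = 1.96,
                                                occipital = 0.76,
                                                parietal = 1.66,
                                                grey_matter = 1.87,
                                                brain_gmwm = 1.90),
                          subject_sd = 0.06,
                          pair_sd = c(thalamus = 0.0486, putamen = 0.0461,
                                      temporal = 0.0241, frontal = 0.0274,
                                      occipital = 0.0291, parietal = 0.0236,
                                      grey_matter = 0.0179,
                                      brain_gmwm = 0.0177),
                          r1_mean = 1.0, r1_sd = 0.05, k2_ref = 0.10,
                          age_range = c(22, 65),
                          sex_prop = c(male = 38, female = 38) / 76,
                          handedness_prop = c(right = 59, left = 8,
                                              unknown = 9) / 76,
                          activity_meanlog = c(Manchester = log(679),
                                               Turku = log(496)),
                          activity_sdlog = c(Manchester = 0.214,
                                             Turku = 0.026),
                          weight_mean = 75, weight_sd = 12,
                          vol_ml = c(thalamus = 15, putamen = 10,
                                     temporal = 180, frontal = 300,
                                     occipital = 140, parietal = 180,
                                     grey_matter = 1300, brain_gmwm = 2400),
                          vol_asym_pct = c(thalamus = -3, putamen = -3,
                                           temporal = 3, frontal = 3,
                                           occipital = 3, parietal = 0,
                                           grey_matter = 2, brain_gmwm = 2),
                          vol_cv = 0.05,
                          suv_asym_pct = 1.0,
                          amp_scale = 12, lam1 = 0.05, lam2 = 0.5,
                          noise_alpha = 0.1,
                          age_slope = 0, sex_effect = 0, hand_effect = 0,
                          centre_effect = c(Manchester = 0, Turku = 0),
                          seed = 1L) {
  regions <- names(baseline_dvr)
  if (is.null(regions) || any(regions == ""))
    stop("`baseline_dvr` must be a fully named vector")
  if (length(asym_rel_diff_pct) == 1 && is.null(names(asym_rel_diff_pct)))
    asym_rel_diff_pct <- stats::setNames(rep(asym_rel_diff_pct,
                                             length(regions)), regions)
  if (length(pair_sd) == 1 && is.null(names(pair_sd)))
    pair_sd <- stats::setNames(rep(pair_sd, length(regions)), regions)
  cfg <- list(n_per_centre = n_per_centre, baseline_dvr = baseline_dvr,
              asym_rel_diff_pct = asym_rel_diff_pct[regions],
              subject_sd = subject_sd, pair_sd = pair_sd[regions],
              r1_mean = r1_mean, r1_sd = r1_sd, k2_ref = k2_ref,
              age_range = age_range, sex_prop = sex_prop,
              handedness_prop = handedness_prop,
              activity_meanlog = activity_meanlog,
              activity_sdlog = activity_sdlog,
              weight_mean = weight_mean, weight_sd = weight_sd,
              vol_ml = vol_ml[regions], vol_asym_pct = vol_asym_pct[regions],
              vol_cv = vol_cv, suv_asym_pct = suv_asym_pct,
              amp_scale = amp_scale, lam1 = lam1, lam2 = lam2,
              noise_alpha = noise_alpha,
              age_slope = age_slope, sex_effect = sex_effect,
              hand_effect = hand_effect, centre_effect = centre_effect,
              regions = regions, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$n_per_centre < 0) || any(cfg$n_per_centre != round(cfg$n_per_centre)))
    stop("subject counts must be non-negative integers")
  if (sum(cfg$n_per_centre) == 0 && any(cfg$asym_rel_diff_pct != 0))
    stop("non-zero asymmetry configured for an empty cohort")
  if (any(cfg$baseline_dvr <= 0)) stop("`baseline_dvr` values must be positive")
  if (any(is.na(cfg$asym_rel_diff_pct)))
    stop("`asym_rel_diff_pct` must name every region in `baseline_dvr`")
  if (any(abs(cfg$asym_rel_diff_pct) >= 200))
    stop("|asym_rel_diff_pct| must be below 200")
  if (any(is.na(cfg$pair_sd)) || any(cfg$pair_sd < 0))
    stop("`pair_sd` must be non-negative for every region")
  if (cfg$subject_sd < 0) stop("`subject_sd` must be non-negative")
  if (abs(sum(cfg$sex_prop) - 1) > 1e-6)
    stop("`sex_prop` must sum to 1")
  if (abs(sum(cfg$handedness_prop) - 1) > 1e-6)
    stop("`handedness_prop` must sum to 1")
  if (cfg$noise_alpha < 0) stop("`noise_alpha` must be non-negative")
  cfg
}

# Largest-remainder allocation of n into round(n * prop) integer counts.
alloc_counts <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws subjects, covariates and ground-truth kinetic parameters.  Each
#' subject consumes its own RNG stream derived from the master seed and the
#' subject index, so enlarging the cohort never reshuffles earlier subjects.
#' For each region the true side DVRs are
#' `DVR_bilat * (1 +/- delta/2)` where `delta` is the configured relative
#' difference plus a Gaussian paired residual of SD `pair_sd`, so the
#' configured relative difference is exact in expectation on the DVR scale.
#' `DVR = BP_ND + 1` holds exactly throughout, and `k2 = R1 * k2_ref`.
#'
#' @param config a [cohort_config].
#' @return list with elements `subjects` (one row per subject: id, centre,
#'   age, sex, handedness, injected activity, body weight) and `truth`
#'   (list: `params` -- subject x region x side SRTM truth, `volumes`,
#'   `intercept`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- sum(config$n_per_centre)
  centres <- rep(names(config$n_per_centre), config$n_per_centre)
  ids <- sprintf("S%03d", seq_len(n))
  regions <- config$regions

  # cohort-level stream: exact-count covariate class assignment
  sex <- rep(names(config$sex_prop), alloc_counts(n, config$sex_prop))
  hand <- rep(names(config$handedness_prop),
              alloc_counts(n, config$handedness_prop))
  perm <- with_seed(derive_seed(config$seed, 0), {
    list(sex = sample.int(n), hand = sample.int(n))
  })
  sex <- sex[perm$sex]
  hand <- hand[perm$hand]

  R <- length(regions)
  age <- wt <- act <- intercept <- numeric(n)
  dvr_l <- dvr_r <- r1_l <- r1_r <- vol_l <- vol_r <- matrix(0, n, R)
  va_l <- config$vol_ml / 2 * (1 - config$vol_asym_pct / 200)
  va_r <- config$vol_ml / 2 * (1 + config$vol_asym_pct / 200)
  for (i in seq_len(n)) {
    with_seed(derive_seed(config$seed, i), {
      age[i] <- stats::runif(1, config$age_range[1], config$age_range[2])
      wt[i] <- min(max(stats::rnorm(1, config$weight_mean,
                                     config$weight_sd), 45), 120)
      act[i] <- stats::rlnorm(1, config$activity_meanlog[[centres[i]]],
                               config$activity_sdlog[[centres[i]]])
      b <- stats::rnorm(1, 0, config$subject_sd)
      intercept[i] <- b
      shift <- config$age_slope * age[i] +
        config$sex_effect * (sex[i] == "male") +
        config$hand_effect * (hand[i] == "right") +
        config$centre_effect[[centres[i]]]
      dvr_b <- config$baseline_dvr + b + shift
      delta <- dvr_b * config$asym_rel_diff_pct / 100 +
        stats::rnorm(R, 0, config$pair_sd)
      dvr_l[i, ] <- dvr_b - delta / 2
      dvr_r[i, ] <- dvr_b + delta / 2
      r1_l[i, ] <- stats::rnorm(R, config$r1_mean, config$r1_sd)
      r1_r[i, ] <- stats::rnorm(R, config$r1_mean, config$r1_sd)
      vol_l[i, ] <- va_l * (1 + stats::rnorm(R, 0, config$vol_cv))
      vol_r[i, ] <- va_r * (1 + stats::rnorm(R, 0, config$vol_cv))
    })
  }
  subjects <- data.frame(subject_id = ids, centre = centres, age = age,
                         sex = sex, handedness = hand,
                         injected_activity_MBq = act, body_weight_kg = wt)
  # long truth table: rows ordered subject, region, side(left, right)
  idx_s <- rep(seq_len(n), each = 2 * R)
  idx_r <- rep(rep(seq_len(R), each = 2), n)
  left <- rep(c(TRUE, FALSE), n * R)
  pick <- function(L, Rm) ifelse(left, t(L)[cbind(idx_r, idx_s)],
                                 t(Rm)[cbind(idx_r, idx_s)])
  dvr <- pick(dvr_l, dvr_r)
  r1 <- pick(r1_l, r1_r)
  params <- data.frame(subject_id = ids[idx_s], region = regions[idx_r],
                       side = ifelse(left, "left", "right"), R1 = r1,
                       k2 = r1 * config$k2_ref, BP_ND = dvr - 1, DVR = dvr)
  volumes <- data.frame(subject_id = ids[idx_s], region = regions[idx_r],
                        side = ifelse(left, "left", "right"),
                        volume_ml = pick(vol_l, vol_r))
  truth <- list(params = params, volumes = volumes,
                intercept = stats::setNames(intercept, ids))
  list(subjects = subjects, truth = truth)
}

#' Simulate all target TACs of one subject
#'
#' Noiseless SRTM forward model ([srtm_forward]) at the subject's true
#' parameters for every region and side in the truth table; the bilateral
#' cerebellum entry is the reference itself.
#'
#' @param subject_id subject identifier present in `truth$params`.
#' @param truth the `truth` element of [generate_cohort].
#' @param schedule the subject's [frame_schedule].
#' @param ref the reference-region [tac].
#' @param regions regions to simulate; default all in the truth table.
#' @return named list of [tac]s, keyed `region.side`, plus
#'   `cerebellum_gm.bilateral`.
#' @export
simulate_subject_tacs <- function(subject_id, truth, schedule, ref,
                                  regions = NULL) {
  p <- truth$params[truth$params$subject_id == subject_id, ]
  if (nrow(p) == 0) stop("no truth rows for subject ", subject_id)
  regions <- regions %||% unique(p$region)
  missing <- setdiff(regions, p$region)
  if (length(missing))
    stop("truth table lacks region(s): ", paste(missing, collapse = ", "),
         " for subject ", subject_id)
  out <- list()
  for (rg in regions) {
    for (sd in c("left", "right")) {
      row <- p[p$region == rg & p$side == sd, ]
      pars <- srtm_params(row$R1, row$k2, row$BP_ND)
      out[[paste(rg, sd, sep = ".")]] <-
        srtm_forward(pars, ref, schedule, label = paste(rg, sd, sep = "."))
    }
  }
  out[["cerebellum_gm.bilateral"]] <- ref
  out
}
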