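#' Run configuration for the end-to-end analysis
#'
#' Bundles everything [run_full_analysis] needs: the input mode (synthetic
#' cohort, tabular TAC files, or a NIfTI image set), the fitting options,
#' the statistics options and the seed.  Exactly one mode is active; the
#' seed is recorded in every artefact.
#'
#' @param mode `"synthetic"` (default), `"tabular"` or `"image"`.
#' @param cohort a [cohort_config] (synthetic mode).
#' @param paths named list for tabular mode (`tacs`, `subjects`, optionally
#'   `volumes`) or image mode (`image`, `labels`, `pmap`, `sidecar`,
#'   `subjects`).
#' @param regions regions to analyse; default all in the cohort config.
#' @param weights `"duration"` or `"uniform"` frame weighting.
#' @param grid k2a search grid, default [srtm_k2a_grid].
#' @param alpha two-sided significance threshold.
#' @param seed run seed; overrides the cohort config's seed when given.
#' @param out_dir optional output directory for artefacts.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "tabular", "image"),
                       cohort = cohort_config(), paths = NULL,
                       regions = NULL, weights = c("duration", "uniform"),
                       grid = srtm_k2a_grid(), alpha = 0.05,
                       seed = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  if (mode != "synthetic" && is.null(paths))
    stop("`paths` is required in ", mode, " mode")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(mode = mode, cohort = cohort, paths = paths,
                 regions = regions %||% cohort$regions, weights = weights,
                 grid = grid, alpha = alpha, seed = cohort$seed,
                 out_dir = out_dir),
            class = "run_config")
}

centre_schedule <- function(centre) {
  if (identical(centre, "Manchester")) manchester_schedule() else turku_schedule()
}

# Simulate (reference + targets, with noise) and fit one subject.
# Returns a list of RegionMeasurement rows plus the cerebellar SUV pair.
simulate_and_fit_subject <- function(i, subj, truth, config, regions,
                                     noise = TRUE, grid = srtm_k2a_grid(),
                                     weights = "duration") {
  sched <- centre_schedule(subj$centre)
  amp <- config$amp_scale * subj$injected_activity_MBq / subj$body_weight_kg
  ref_clean <- simulate_reference_tac(sched, amp, config$lam1, config$lam2)
  s <- config$suv_asym_pct / 200
  cer_l <- tac(sched, ref_clean$values * (1 - s), label = "cerebellum_gm.left")
  cer_r <- tac(sched, ref_clean$values * (1 + s), label = "cerebellum_gm.right")
  if (noise && config$noise_alpha > 0) {
    cer_l <- add_tac_noise(cer_l, config$noise_alpha,
                           derive_seed(config$seed, i, 101))
    cer_r <- add_tac_noise(cer_r, config$noise_alpha,
                           derive_seed(config$seed, i, 102))
  }
  ref_meas <- tac(sched, (cer_l$values + cer_r$values) / 2,
                  label = "cerebellum_gm.bilateral")
  w <- default_weights(sched, weights)
  basis <- srtm_basis(ref_meas, grid)
  p <- truth$params[truth$params$subject_id == subj$subject_id, ]
  rows <- list()
  for (k in seq_along(regions)) {
    rg <- regions[k]
    for (sd_i in 1:2) {
      side <- c("left", "right")[sd_i]
      row <- p[p$region == rg & p$side == side, ]
      if (nrow(row) == 0) stop("truth table lacks region ", rg)
      tc <- srtm_forward(srtm_params(row$R1, row$k2, row$BP_ND),
                         ref_clean, sched)
      if (noise && config$noise_alpha > 0)
        tc <- add_tac_noise(tc, config$noise_alpha,
                            derive_seed(config$seed, i, 2 * k + sd_i * 211))
      fit <- fit_srtm(tc, ref_meas, weights = w, grid = grid, basis = basis)
      cf <- coef(fit)
      rows[[length(rows) + 1]] <-
        data.frame(subject_id = subj$subject_id, region = rg, side = side,
                   R1 = cf[["R1"]], k2 = cf[["k2"]], BP_ND = cf[["BP_ND"]],
                   DVR = cf[["DVR"]], wrss = fit$wrss,
                   boundary = fit$boundary, degenerate = fit$degenerate)
    }
  }
  suv <- c(left = suv_window(cer_l, subj$injected_activity_MBq,
                             subj$body_weight_kg)$value,
           right = suv_window(cer_r, subj$injected_activity_MBq,
                              subj$body_weight_kg)$value)
  list(fits = do.call(rbind, rows), suv = suv)
}

#' Simulate and kinetically quantify a synthetic cohort
#'
#' Generates the cohort of `config`, simulates per-subject reference and
#' target TACs on the centre-specific frame schedules, adds frame-variance
#' noise, fits the SRTM per region and side against the measured bilateral
#' cerebellar reference, and assembles the long region-measurement table
#' (one row per subject x region x side: DVR, R1, volume) plus the
#' cerebellar SUV pair per subject.
#'
#' @param config a [cohort_config].
#' @param regions subset of regions to quantify (default all).
#' @param noise apply TAC noise (FALSE gives the noiseless pipeline).
#' @param grid,weights fitting options as in [fit_srtm].
#' @return list: `cohort` (subjects + truth), `measurements` (long data
#'   frame), `suv` (subject_id, SUV_left, SUV_right).
#' @export
quantify_cohort <- function(config, regions = config$regions, noise = TRUE,
                            grid = srtm_k2a_grid(),
                            weights = "duration") {
  cohort <- generate_cohort(config)
  n <- nrow(cohort$subjects)
  fits <- vector("list", n)
  suv <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- cohort$subjects[i, ]
    res <- simulate_and_fit_subject(i, subj, cohort$truth, config, regions,
                                    noise = noise, grid = grid,
                                    weights = weights)
    fits[[i]] <- res$fits
    suv[[i]] <- data.frame(subject_id = subj$subject_id,
                           SUV_left = res$suv[["left"]],
                           SUV_right = res$suv[["right"]])
  }
  meas <- do.call(rbind, fits)
  meas <- merge(meas, cohort$truth$volumes,
                by = c("subject_id", "region", "side"), sort = FALSE)
  meas <- merge(meas, cohort$subjects[, c("subject_id", "centre", "age",
                                          "sex", "handedness")],
                by = "subject_id", sort = FALSE)
  list(cohort = cohort, measurements = meas, suv = do.call(rbind, suv))
}

#' Pivot region measurements to one row per subject and region
#'
#' @param meas long measurement table (columns `subject_id`, `region`,
#'   `side`, and the `values` columns).
#' @param values measurement columns to pair.
#' @return paired data frame with `<value>_left` / `<value>_right` columns.
#' @export
pair_measurements <- function(meas, values = c("DVR", "R1", "volume_ml")) {
  values <- intersect(values, names(meas))
  keep <- c("subject_id", "region", "side", values,
            intersect(c("centre", "age", "sex", "handedness"), names(meas)))
  wide <- stats::reshape(meas[, keep], direction = "wide",
                         idvar = c("subject_id", "region",
                                   intersect(c("centre", "age", "sex",
                                               "handedness"), names(meas))),
                         timevar = "side", v.names = values, sep = "_")
  rownames(wide) <- NULL
  wide
}

fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full asymmetry analysis
#'
#' Executes every stage in order -- simulate (or ingest) TACs, fit the SRTM
#' per region and side, compute laterality metrics, run the inferential
#' battery -- and returns a machine-readable report mirroring the shape of
#' the study's summary tables: pooled and per-centre per-region DVR
#' summaries with Wilcoxon and Mann-Whitney p-values (Holm-Sidak adjusted
#' within each battery), hemispheric R1 and cerebellar SUV asymmetry,
#' volume-vs-DVR asymmetry correlations, and the global plus per-region
#' random-intercept mixed models.  Identical config and seed yield an
#' identical report.
#'
#' @param config a [run_config].
#' @return an object of class `"asym_report"`; see [write_report] for the
#'   serialised form.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cc <- config$cohort
  cc$seed <- config$seed

  if (config$mode == "synthetic") {
    q <- quantify_cohort(cc, regions = config$regions,
                         grid = config$grid, weights = config$weights)
    subjects <- q$cohort$subjects
    meas <- q$measurements
    suv <- q$suv
  } else if (config$mode == "tabular") {
    tt <- read_tac_table(config$paths$tacs)
    subjects <- read_subject_table(config$paths$subjects)
    q <- fit_tac_table(tt, subjects, grid = config$grid,
                       weights = config$weights)
    meas <- q$measurements
    if (!is.null(config$paths$volumes)) {
      vols <- utils::read.csv(config$paths$volumes)
      meas <- merge(meas, vols, by = c("subject_id", "region", "side"),
                    sort = FALSE)
    }
    meas <- merge(meas, subjects[, c("subject_id", "centre", "age", "sex",
                                     "handedness")],
                  by = "subject_id", sort = FALSE)
    suv <- q$suv
  } else {
    # image mode: a manifest CSV lists one NIfTI set per subject
    man <- utils::read.csv(config$paths$manifest, stringsAsFactors = FALSE)
    need <- c("subject_id", "image", "labels", "pmap", "sidecar")
    miss <- setdiff(need, names(man))
    if (length(miss)) stop("image manifest lacks column(s): ",
                           paste(miss, collapse = ", "))
    subjects <- read_subject_table(config$paths$subjects)
    ex <- lapply(seq_len(nrow(man)), function(i)
      image_to_tac_table(man$image[i], man$labels[i], man$pmap[i],
                         man$sidecar[i], man$subject_id[i]))
    tt <- do.call(rbind, lapply(ex, `[[`, "tacs"))
    q <- fit_tac_table(tt, subjects, grid = config$grid,
                       weights = config$weights)
    meas <- q$measurements
    vols <- do.call(rbind, lapply(ex, `[[`, "volumes"))
    meas <- merge(meas, vols, by = c("subject_id", "region", "side"),
                  sort = FALSE)
    meas <- merge(meas, subjects[, c("subject_id", "centre", "age", "sex",
                                     "handedness")],
                  by = "subject_id", sort = FALSE)
    suv <- q$suv
  }

  regions <- intersect(config$regions, unique(meas$region))
  paired <- pair_measurements(meas)
  paired <- paired[paired$region %in% regions, ]

  # pooled and per-centre DVR asymmetry (regions are one Holm-Sidak family)
  dvr_pooled <- summarize_asymmetry(paired)
  by_centre <- lapply(split(paired, paired$centre), summarize_asymmetry)
  # between-centre comparison per region and side
  centres <- unique(paired$centre)
  between <- NULL
  if (length(centres) == 2) {
    rows <- list()
    for (rg in regions) for (side in c("left", "right")) {
      col <- paste0("DVR_", side)
      a <- paired[paired$region == rg & paired$centre == centres[1], col]
      b <- paired[paired$region == rg & paired$centre == centres[2], col]
      mw <- mann_whitney_u(a, b)
      rows[[paste(rg, side)]] <- data.frame(region = rg, side = side,
                                            U = mw$statistic,
                                            p_raw = mw$p_raw)
    }
    between <- do.call(rbind, rows)
    between$p_adjusted <- holm_sidak_adjust(between$p_raw)
    rownames(between) <- NULL
  }

  # R1 asymmetry (reported alongside DVR)
  r1_summary <- summarize_asymmetry(paired, value = "R1")
  # volumes and volume-vs-DVR asymmetry correlation
  vol_summary <- NULL; correlations <- NULL
  if ("volume_ml_left" %in% names(paired)) {
    vol_summary <- summarize_asymmetry(paired, value = "volume_ml")
    rows <- lapply(regions, function(rg) {
      d <- paired[paired$region == rg, ]
      ct <- pearson_correlation(
        asymmetry_index(d$volume_ml_left, d$volume_ml_right),
        asymmetry_index(d$DVR_left, d$DVR_right))
      data.frame(region = rg, r = ct$statistic, p = ct$p_raw, n = ct$n)
    })
    correlations <- do.call(rbind, rows)
    rownames(correlations) <- NULL
  }
  # cerebellar SUV asymmetry
  suv_summary <- NULL
  if (!is.null(suv) && nrow(suv) >= 2) {
    wt <- wilcoxon_signed_rank(suv$SUV_right, suv$SUV_left)
    suv_summary <- data.frame(region = "cerebellum_gm", n = nrow(suv),
                              median_left = stats::median(suv$SUV_left),
                              median_right = stats::median(suv$SUV_right),
                              rel_diff_pct = 100 * mean(suv$SUV_right - suv$SUV_left) /
                                mean(c(mean(suv$SUV_left), mean(suv$SUV_right))),
                              cohens_d = paired_cohens_d(suv$SUV_left,
                                                         suv$SUV_right),
                              p_wilcoxon = wt$p_raw)
  }

  # mixed models: global (GMWM if analysed, else first region), per region
  lme_global <- NULL; lme_regional <- NULL
  glob_rg <- if ("brain_gmwm" %in% regions) "brain_gmwm" else regions[1]
  long <- meas[meas$region %in% regions,
               c("subject_id", "centre", "age", "sex", "handedness",
                 "region", "side", "DVR")]
  names(long)[names(long) == "side"] <- "hemisphere"
  enough <- length(unique(long$subject_id[long$handedness != "unknown"])) >= 10
  if (enough && length(centres) >= 2) {
    lme_global <- fit_lme_random_intercept(long[long$region == glob_rg, ])
    reg6 <- setdiff(regions, c("grey_matter", "brain_gmwm"))
    if (length(reg6) > 0)
      lme_regional <- fit_lme_by_region(long[long$region %in% reg6, ])
  }

  cfg_json <- jsonlite::toJSON(config[c("mode", "regions", "weights",
                                        "alpha", "seed")],
                               auto_unbox = TRUE, digits = NA)
  report <- list(
    provenance = list(package = "petasym",
                      version = as.character(utils::packageVersion("petasym")),
                      seed = config$seed, mode = config$mode,
                      config_hash = fnv1a_hash(as.character(cfg_json)),
                      k2a_grid = range(config$grid),
                      k2a_grid_n = length(config$grid),
                      weights = config$weights, alpha = config$alpha,
                      n_subjects = nrow(subjects),
                      n_per_centre = table(subjects$centre),
                      n_unknown_handedness =
                        sum(subjects$handedness == "unknown")),
    dvr_pooled = dvr_pooled,
    dvr_by_centre = by_centre,
    between_centre = between,
    r1_summary = r1_summary,
    suv_summary = suv_summary,
    volume_summary = vol_summary,
    volume_dvr_correlation = correlations,
    lme_global = if (!is.null(lme_global))
      lme_global[c("fixed", "varcomp", "n_subjects", "n_rows",
                   "n_excluded", "df_method")],
    lme_regional = lme_regional,
    measurements = meas,
    suv = suv,
    subjects = subjects)
  class(report) <- "asym_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.asym_report <- function(x, ...) {
  pv <- x$provenance
  cat("PET hemispheric-asymmetry report (seed ", pv$seed, ", ", pv$mode,
      " mode, ", pv$n_subjects, " subjects)\n\n", sep = "")
  print(x$dvr_pooled)
  if (!is.null(x$lme_global)) {
    h <- x$lme_global$fixed
    h <- h[h$term == "hemisphereright", ]
    cat(sprintf("\nLME hemisphere (right vs left) estimate: %.4f [%.4f, %.4f], p = %s\n",
                h$estimate, h$ci_lo, h$ci_hi, format.pval(h$p)))
  }
  invisible(x)
}

#' Serialise a report
#'
#' Writes `report.json` (schema: provenance, summaries, model tables; every
#' p-value column carries its adjustment status in its name) plus CSV
#' artefacts (`measurements.csv`, `subjects.csv`, `suv.csv`).  Identical
#' reports serialise byte-identically.
#'
#' @param report an `"asym_report"`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- unclass(report)
  slim$measurements <- NULL; slim$subjects <- NULL; slim$suv <- NULL
  slim$dvr_pooled <- as.data.frame(slim$dvr_pooled)
  slim$dvr_by_centre <- lapply(slim$dvr_by_centre, as.data.frame)
  slim$r1_summary <- as.data.frame(slim$r1_summary)
  if (!is.null(slim$volume_summary))
    slim$volume_summary <- as.data.frame(slim$volume_summary)
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  write_csv_full(report$measurements, file.path(dir, "measurements.csv"))
  write_csv_full(report$subjects, file.path(dir, "subjects.csv"))
  if (!is.null(report$suv))
    write_csv_full(report$suv, file.path(dir, "suv.csv"))
  invisible(file.path(dir, "report.json"))
}
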