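# Tabular I/O: long TAC tables, subject metadata, cohort artefacts.
# Numeric columns are written with 17 significant digits so a write -> read
# round trip is lossless at double precision.

write_csv_full <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

tac_table_cols <- c("subject_id", "region", "side", "frame_start_min",
                    "frame_end_min", "value_kBq_per_mL")

#' Read and validate a long TAC table
#'
#' The documented schema is one row per subject x region x side x frame
#' with columns `subject_id, region, side, frame_start_min, frame_end_min,
#' value_kBq_per_mL`.  Duplicate frame rows, non-monotone or overlapping
#' frames are rejected with the offending subject and row numbers.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_tac_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("unreadable TAC table (", path,
                                          "): expected schema columns ",
                                          paste(tac_table_cols, collapse = ", ")))
  miss <- setdiff(tac_table_cols, names(df))
  if (length(miss))
    stop("TAC table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty TAC table: no data rows")
  key <- interaction(df$subject_id, df$region, df$side, df$frame_start_min,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("duplicated subject x region x side x frame rows: ",
         paste(utils::head(rows, 5), collapse = ", "))
  }
  sp <- split(seq_len(nrow(df)),
              interaction(df$subject_id, df$region, df$side, drop = TRUE))
  for (idx in sp) {
    o <- idx[order(df$frame_start_min[idx])]
    st <- df$frame_start_min[o]; en <- df$frame_end_min[o]
    if (any(en <= st))
      stop("frame with end <= start for subject ", df$subject_id[o[1]],
           " (row ", o[which(en <= st)[1]], ")")
    if (length(o) > 1 && any(st[-1] < en[-length(en)]))
      stop("overlapping frames for subject ", df$subject_id[o[1]],
           " (row ", o[1 + which(st[-1] < en[-length(en)])[1]], ")")
  }
  df
}

#' @rdname read_tac_table
#' @param df a long TAC table (e.g. from [tacs_to_table]).
#' @export
write_tac_table <- function(df, path) {
  miss <- setdiff(tac_table_cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  write_csv_full(df[, tac_table_cols], path)
}

#' Convert a named list of TACs to the long table form
#'
#' @param tacs named list of [tac]s keyed `region.side` (as returned by
#'   [simulate_subject_tacs]).
#' @param subject_id subject identifier for the rows.
#' @return long data frame in the [read_tac_table] schema.
#' @export
tacs_to_table <- function(tacs, subject_id) {
  rows <- lapply(names(tacs), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    x <- tacs[[key]]
    data.frame(subject_id = subject_id, region = parts[1], side = parts[2],
               frame_start_min = x$schedule$start,
               frame_end_min = x$schedule$end,
               value_kBq_per_mL = x$values)
  })
  do.call(rbind, rows)
}

subject_cols <- c("subject_id", "centre", "age", "sex", "handedness",
                  "injected_activity_MBq", "body_weight_kg")

#' @rdname read_tac_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(subject_cols, names(df))
  if (length(miss))
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$age <= 0) || any(df$injected_activity_MBq <= 0) ||
      any(df$body_weight_kg <= 0))
    stop("age, injected activity and body weight must be positive")
  df
}

#' Persist a synthetic cohort as plain-text artefacts
#'
#' Writes `subjects.csv` (metadata), `tacs.csv` (long TAC table including
#' the bilateral cerebellar reference) and `truth.json` (ground-truth
#' parameters and volumes) into `dir`.
#'
#' @param config a [cohort_config].
#' @param dir output directory.
#' @param noise apply TAC noise before writing.
#' @return (invisibly) named vector of file paths.
#' @export
write_cohort_csv <- function(config, dir, noise = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  tabs <- vector("list", nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    subj <- cohort$subjects[i, ]
    sched <- centre_schedule(subj$centre)
    amp <- config$amp_scale * subj$injected_activity_MBq / subj$body_weight_kg
    ref <- simulate_reference_tac(sched, amp, config$lam1, config$lam2)
    tacs <- simulate_subject_tacs(subj$subject_id, cohort$truth, sched, ref)
    if (noise && config$noise_alpha > 0)
      tacs <- lapply(stats::setNames(names(tacs), names(tacs)), function(key)
        add_tac_noise(tacs[[key]], config$noise_alpha,
                      derive_seed(config$seed, i, match(key, names(tacs)))))
    tabs[[i]] <- tacs_to_table(tacs, subj$subject_id)
  }
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             tacs = file.path(dir, "tacs.csv"),
             truth = file.path(dir, "truth.json"))
  write_csv_full(cohort$subjects, paths["subjects"])
  write_tac_table(do.call(rbind, tabs), paths["tacs"])
  jsonlite::write_json(list(seed = config$seed,
                            params = cohort$truth$params,
                            volumes = cohort$truth$volumes),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Fit SRTM to every subject of a long TAC table
#'
#' Groups the table by subject, uses the `cerebellum_gm`/`bilateral` rows as
#' the reference input and fits every other region x side TAC with
#' [fit_srtm]; cerebellar left/right rows (if present) yield the SUV pair.
#'
#' @param tt validated TAC table ([read_tac_table]).
#' @param subjects subject metadata ([read_subject_table]).
#' @inheritParams fit_srtm
#' @param weights `"duration"` or `"uniform"`.
#' @return list: `measurements` (long fit table), `suv`.
#' @export
fit_tac_table <- function(tt, subjects, grid = srtm_k2a_grid(),
                          weights = "duration") {
  out <- list(); suv <- list()
  for (sid in unique(tt$subject_id)) {
    d <- tt[tt$subject_id == sid, ]
    refrows <- d[d$region == "cerebellum_gm" & d$side == "bilateral", ]
    if (nrow(refrows) == 0)
      stop("subject ", sid, " has no bilateral cerebellar reference TAC")
    o <- order(refrows$frame_start_min)
    sched <- new_frame_schedule(refrows$frame_start_min[o],
                                refrows$frame_end_min[o])
    ref <- tac(sched, refrows$value_kBq_per_mL[o])
    w <- default_weights(sched, weights)
    basis <- srtm_basis(ref, grid)
    meta <- subjects[subjects$subject_id == sid, ]
    for (key in unique(paste(d$region, d$side))) {
      parts <- strsplit(key, " ")[[1]]
      if (parts[1] == "cerebellum_gm" && parts[2] == "bilateral") next
      rows <- d[d$region == parts[1] & d$side == parts[2], ]
      o <- order(rows$frame_start_min)
      tc <- tac(sched, rows$value_kBq_per_mL[o])
      if (parts[1] == "cerebellum_gm") {
        if (nrow(meta) == 1)
          suv[[paste(sid, parts[2])]] <-
            data.frame(subject_id = sid, side = parts[2],
                       SUV = suv_window(tc, meta$injected_activity_MBq,
                                        meta$body_weight_kg)$value)
        next
      }
      fit <- fit_srtm(tc, ref, weights = w, grid = grid, basis = basis)
      cf <- coef(fit)
      out[[paste(sid, key)]] <-
        data.frame(subject_id = sid, region = parts[1], side = parts[2],
                   R1 = cf[["R1"]], k2 = cf[["k2"]], BP_ND = cf[["BP_ND"]],
                   DVR = cf[["DVR"]], wrss = fit$wrss,
                   boundary = fit$boundary, degenerate = fit$degenerate)
    }
  }
  suv_df <- NULL
  if (length(suv)) {
    long <- do.call(rbind, suv)
    suv_df <- stats::reshape(long, direction = "wide", idvar = "subject_id",
                             timevar = "side", v.names = "SUV", sep = "_")
    rownames(suv_df) <- NULL
  }
  list(measurements = do.call(rbind, out), suv = suv_df)
}

#' Extract a TAC table from a NIfTI image set
#'
#' Image-mode entry point: reads the 4D dynamic image, label volume,
#' grey-matter probability map and JSON schedule sidecar (as written by
#' [write_phantom_nifti]), binarizes the probability map at 0.5, extracts
#' the per-label TACs and volumes, and returns a tabular-mode TAC table
#' plus a volume table.
#'
#' @param image,labels,pmap,sidecar file paths.
#' @param subject_id identifier for the emitted rows.
#' @return list: `tacs` (long TAC table), `volumes`.
#' @export
image_to_tac_table <- function(image, labels, pmap, sidecar, subject_id) {
  img <- read_nifti_volume(image)
  lab <- read_nifti_volume(labels)
  pm <- read_nifti_volume(pmap)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sched <- new_frame_schedule(side$frame_start_min, side$frame_end_min)
  legend <- unlist(side$legend)
  vs <- attr(lab, "voxel_size_mm")
  gm_mask <- binarize_probability_map(pm)
  labv <- label_volume(array(as.integer(round(lab)), dim(lab)), vs,
                       legend = legend)
  gm_regions <- c("temporal", "frontal", "occipital", "parietal",
                  "grey_matter", "cerebellum_gm")
  rows <- list(); vols <- list()
  for (key in names(legend)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    def <- region_definition(parts[1], parts[2], legend[[key]])
    mask <- combine_region_labels(labv, def,
                                  gm_mask = if (def$tissue == "GM") gm_mask)
    ex <- extract_region_tac(img, mask, vs, sched, label = key)
    rows[[key]] <- data.frame(subject_id = subject_id, region = parts[1],
                              side = parts[2],
                              frame_start_min = sched$start,
                              frame_end_min = sched$end,
                              value_kBq_per_mL = ex$tac$values)
    vols[[key]] <- data.frame(subject_id = subject_id, region = parts[1],
                              side = parts[2], volume_ml = ex$volume_ml)
  }
  cer <- names(legend)[startsWith(names(legend), "cerebellum_gm")]
  if (length(cer) == 2) {
    l <- rows[[cer[1]]]$value_kBq_per_mL; r <- rows[[cer[2]]]$value_kBq_per_mL
    rows[["cerebellum_gm.bilateral"]] <-
      data.frame(subject_id = subject_id, region = "cerebellum_gm",
                 side = "bilateral", frame_start_min = sched$start,
                 frame_end_min = sched$end, value_kBq_per_mL = (l + r) / 2)
  }
  list(tacs = do.call(rbind, rows), volumes = do.call(rbind, vols))
}
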