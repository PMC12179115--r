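#' Digital phantom for the image-mode pipeline
#'
#' Builds a small 4D dynamic image with mirror-placed left/right blobs for
#' each of six bilateral regions plus a bilateral cerebellar blob, a label
#' volume, and a grey-matter probability map.  Each blob's voxels carry the
#' SRTM forward TAC of that region and side at the supplied ground-truth
#' parameters (plus optional frame-variance noise per voxel), so
#' [extract_region_tac] reproduces the generating TAC exactly in the
#' noiseless case.  The probability map is 1 inside GM blobs and 0 outside;
#' a one-voxel boundary shell around GM blobs carries `shell_p`, straddling
#' the 0.5 threshold when so configured.
#'
#' @param truth the `truth` element of [generate_cohort] (one subject used).
#' @param subject_id subject whose truth parameters drive the blobs.
#' @param schedule acquisition [frame_schedule].
#' @param ref reference-region [tac] (the cerebellar blobs carry it).
#' @param regions bilateral regions to place (default the six named
#'   regions); each needs truth rows for both sides.
#' @param grid_shape integer length 3; must fit the blobs.
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param shell_p probability value of the GM boundary shell.
#' @param noise_alpha per-voxel TAC noise scale (0 = noiseless).
#' @param seed noise seed.
#' @return list: `image4d`, `labels` ([label_volume]), `pmap`
#'   ([probability_map]), `legend` (named label ids, `region.side`), and
#'   `tacs` (the generating noiseless TACs, keyed like the legend).
#' @export
generate_phantom_image <- function(truth, subject_id, schedule, ref,
                                   regions = c("thalamus", "putamen",
                                               "temporal", "frontal",
                                               "occipital", "parietal"),
                                   grid_shape = c(24, 24, 16),
                                   voxel_size_mm = 2,
                                   shell_p = 0.49,
                                   noise_alpha = 0, seed = 1L) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  n_slots <- length(regions) + 1  # + cerebellum
  # blob anchors: 2x2x2 boxes along y/z, mirrored across the x midline
  per_col <- max(1, floor((ny - 2) / 4))
  need_z <- ceiling(n_slots / per_col)
  if (nx < 9 || ny < 6 || nz < 4 * need_z + 2)
    stop("grid too small for ", n_slots, " paired blobs")

  labels <- array(0L, grid_shape)
  pmap_arr <- array(0, grid_shape)
  gm_regions <- c("temporal", "frontal", "occipital", "parietal",
                  "cerebellum_gm")
  legend <- integer(0)
  boxes <- list()
  slot_names <- c(regions, "cerebellum_gm")
  for (k in seq_len(n_slots)) {
    col <- (k - 1) %% per_col
    lay <- (k - 1) %/% per_col
    y0 <- 2 + 4 * col; z0 <- 2 + 4 * lay
    for (s in c("left", "right")) {
      xs <- if (s == "left") 2:3 else (nx - 2):(nx - 1)
      id <- 2L * k - (s == "left")
      key <- paste(slot_names[k], s, sep = ".")
      labels[xs, y0:(y0 + 1), z0:(z0 + 1)] <- id
      legend[[key]] <- id
      boxes[[key]] <- list(x = xs, y = y0:(y0 + 1), z = z0:(z0 + 1))
      if (slot_names[k] %in% gm_regions)
        pmap_arr[xs, y0:(y0 + 1), z0:(z0 + 1)] <- 1
    }
  }
  # boundary shell around GM blobs (6-neighbourhood dilation minus blob)
  gm <- pmap_arr == 1
  shell <- array(FALSE, grid_shape)
  shift1 <- function(a, d, k) {
    out <- array(FALSE, dim(a))
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[d]
    if (k > 0) { idx_dst[[d]] <- (1 + k):n; idx_src[[d]] <- 1:(n - k) }
    else { idx_dst[[d]] <- 1:(n + k); idx_src[[d]] <- (1 - k):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (d in 1:3) for (k in c(-1, 1)) shell <- shell | shift1(gm, d, k)
  shell <- shell & !gm
  pmap_arr[shell] <- shell_p

  # fill the dynamic image
  nfr <- nrow(schedule)
  image4d <- array(0, c(grid_shape, nfr))
  tacs <- list()
  p <- truth$params[truth$params$subject_id == subject_id, ]
  if (nrow(p) == 0) stop("no truth rows for subject ", subject_id)
  vox_i <- 0
  for (key in names(boxes)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    rg <- parts[1]; sd <- parts[2]
    curve <- if (rg == "cerebellum_gm") ref else {
      row <- p[p$region == rg & p$side == sd, ]
      if (nrow(row) == 0) stop("truth table lacks region ", rg)
      srtm_forward(srtm_params(row$R1, row$k2, row$BP_ND), ref, schedule)
    }
    tacs[[key]] <- tac(schedule, curve$values, label = key)
    b <- boxes[[key]]
    for (x in b$x) for (y in b$y) for (z in b$z) {
      vox_i <- vox_i + 1
      v <- if (noise_alpha > 0)
        add_tac_noise(tacs[[key]], noise_alpha,
                      derive_seed(seed, vox_i))$values
      else tacs[[key]]$values
      image4d[x, y, z, ] <- v
    }
  }
  list(image4d = image4d,
       labels = label_volume(labels, voxel_size_mm, legend = legend),
       pmap = probability_map(pmap_arr, voxel_size_mm),
       legend = legend, tacs = tacs)
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti recording the isotropic voxel size in the
#' header.  `write_phantom_nifti` persists a phantom's 4D image, label
#' volume and probability map next to a JSON frame-schedule sidecar.
#'
#' @param phantom output of [generate_phantom_image].
#' @param schedule the phantom's [frame_schedule].
#' @param dir output directory.
#' @return (invisibly) the written file paths.
#' @export
write_phantom_nifti <- function(phantom, schedule, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- attr(phantom$labels, "voxel_size_mm")
  paths <- c(image = file.path(dir, "dynamic.nii.gz"),
             labels = file.path(dir, "labels.nii.gz"),
             pmap = file.path(dir, "gm_probability.nii.gz"),
             sidecar = file.path(dir, "schedule.json"))
  RNifti::writeNifti(RNifti::asNifti(phantom$image4d,
                                     pixdim = c(vs, vs, vs, 1)),
                     paths["image"])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom$labels),
                                           dim(phantom$labels)),
                                     pixdim = rep(vs, 3)),
                     paths["labels"])
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(phantom$pmap),
                                           dim(phantom$pmap)),
                                     pixdim = rep(vs, 3)),
                     paths["pmap"])
  jsonlite::write_json(list(frame_start_min = schedule$start,
                            frame_end_min = schedule$end,
                            legend = as.list(phantom$legend)),
                       paths["sidecar"], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

#' @rdname write_phantom_nifti
#' @param path NIfTI file path.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  arr
}
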