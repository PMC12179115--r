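#' Label volumes and probability maps
#'
#' Minimal containers for already-aligned 3D label images and tissue
#' probability maps (voxel-index space; registration and atlas warping are
#' the caller's responsibility).  `label_volume()` wraps a non-negative
#' integer array (0 = background) with an isotropic voxel size and a legend
#' mapping label ids to names; `probability_map()` wraps a float array with
#' values in [0, 1].
#'
#' @param arr 3D array.
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param legend named integer vector: `legend[["name"]] = label id`.
#' @return classed array.
#' @export
label_volume <- function(arr, voxel_size_mm, legend = NULL) {
  if (length(dim(arr)) != 3) stop("label volume must be a 3D array")
  if (any(arr < 0) || any(arr != round(arr)))
    stop("labels must be non-negative integers")
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  structure(arr, voxel_size_mm = voxel_size_mm, legend = legend,
            class = c("label_volume", class(arr)))
}

#' @rdname label_volume
#' @export
probability_map <- function(arr, voxel_size_mm) {
  if (length(dim(arr)) != 3) stop("probability map must be a 3D array")
  if (any(arr < 0 | arr > 1)) stop("probabilities must lie in [0, 1]")
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  structure(arr, voxel_size_mm = voxel_size_mm,
            class = c("probability_map", class(arr)))
}

#' Threshold a probability map to a binary mask
#'
#' Voxels with probability greater than or equal to the threshold are
#' included (inclusive boundary, so the nominal threshold value itself is
#' inside the mask).
#'
#' @param pmap a [probability_map] (or plain 3D array in [0, 1]).
#' @param threshold in (0, 1); the conventional grey-matter cut is 0.5.
#' @return logical 3D array.
#' @export
binarize_probability_map <- function(pmap, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  if (any(pmap < 0 | pmap > 1)) stop("probabilities must lie in [0, 1]")
  mask <- array(pmap >= threshold, dim = dim(pmap))
  if (!any(mask)) warning("thresholded mask is empty")
  mask
}

#' Region definitions
#'
#' Names a composite region: which atlas labels it unions, which side it
#' lives on, and whether it is read on segmented grey matter (GM; cortices,
#' hemispheric grey matter, cerebellar reference) or on the unsegmented
#' grey+white tissue (GMWM; thalamus, putamen, whole brain).
#'
#' @param name one of `thalamus`, `putamen`, `temporal`, `frontal`,
#'   `occipital`, `parietal`, `grey_matter`, `brain_gmwm`, `cerebellum_gm`.
#' @param side `"left"`, `"right"` or `"bilateral"`.
#' @param member_labels non-empty integer vector of atlas label ids.
#' @param tissue `"GM"` or `"GMWM"`; defaults to the convention above.
#' @export
region_definition <- function(name, side, member_labels, tissue = NULL) {
  name <- match.arg(name, c("thalamus", "putamen", "temporal", "frontal",
                            "occipital", "parietal", "grey_matter",
                            "brain_gmwm", "cerebellum_gm"))
  side <- match.arg(side, c("left", "right", "bilateral"))
  if (length(member_labels) == 0) stop("`member_labels` must be non-empty")
  default_tissue <- if (name %in% c("thalamus", "putamen", "brain_gmwm"))
    "GMWM" else "GM"
  tissue <- tissue %||% default_tissue
  tissue <- match.arg(tissue, c("GM", "GMWM"))
  structure(list(name = name, side = side, tissue = tissue,
                 member_labels = as.integer(member_labels)),
            class = "region_definition")
}

#' Build a region mask from a label volume
#'
#' Unions the member labels of a [region_definition]; GM-tissue regions are
#' intersected with the binarized grey-matter mask when one is supplied.
#'
#' @param labels a [label_volume].
#' @param definition a [region_definition].
#' @param gm_mask optional logical array from [binarize_probability_map].
#' @return logical 3D array.
#' @export
combine_region_labels <- function(labels, definition, gm_mask = NULL) {
  legend <- attr(labels, "legend")
  known <- if (!is.null(legend)) legend else sort(unique(as.vector(labels)))
  unknown <- setdiff(definition$member_labels, known)
  if (length(unknown))
    stop("unknown label id(s): ", paste(unknown, collapse = ", "))
  mask <- array(labels %in% definition$member_labels, dim = dim(labels))
  if (definition$tissue == "GM" && !is.null(gm_mask)) {
    if (!all(dim(gm_mask) == dim(labels)))
      stop("grey-matter mask and label volume differ in shape")
    mask <- mask & gm_mask
  }
  mask
}

#' Extract a region TAC and volume from a dynamic image
#'
#' Per-frame unweighted mean over the mask voxels of a 4D image; the region
#' volume is the voxel count times the voxel volume, in mL.
#'
#' @param image4d 4D array (x, y, z, frame).
#' @param mask logical 3D array on the same grid; must be non-empty.
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param schedule the [frame_schedule] of the dynamic image.
#' @param label tag for the returned TAC.
#' @return list: `tac` (a [tac]) and `volume_ml`.
#' @examples
#' img <- array(2, c(4, 4, 4, 3))
#' m <- array(TRUE, c(4, 4, 4))
#' sch <- frame_schedule(3, 1, units = "min")
#' extract_region_tac(img, m, 1.22, sch)$volume_ml  # 64 * 1.22^3 / 1000
#' @export
extract_region_tac <- function(image4d, mask, voxel_size_mm, schedule,
                               label = NULL) {
  if (length(dim(image4d)) != 4) stop("`image4d` must be a 4D array")
  if (!all(dim(image4d)[1:3] == dim(mask)))
    stop("image and mask do not share a grid")
  nvox <- sum(mask)
  if (nvox == 0) stop("empty mask")
  nfr <- dim(image4d)[4]
  if (nfr != nrow(schedule)) stop("image frames do not match the schedule")
  flat <- matrix(image4d, ncol = nfr)
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE])
  list(tac = tac(schedule, vals, label = label),
       volume_ml = nvox * voxel_size_mm^3 / 1000)
}
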