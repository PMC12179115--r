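test_that("probability-map thresholding is inclusive at the boundary", {
  pm <- array(0, c(3, 3, 3))
  pm[1, 1, 1] <- 0.5
  pm[2, 1, 1] <- 0.49
  pm[3, 1, 1] <- 0.51
  mask <- binarize_probability_map(pm)
  expect_true(mask[1, 1, 1])       # exactly at threshold: included
  expect_false(mask[2, 1, 1])
  expect_true(mask[3, 1, 1])
  expect_equal(sum(mask), 2)
  expect_warning(binarize_probability_map(array(0, c(2, 2, 2))), "empty")
  expect_error(binarize_probability_map(array(1.5, c(2, 2, 2))), "0, 1")
  expect_error(binarize_probability_map(pm, threshold = 0), "0, 1")
})

test_that("label unions combine disjoint regions and respect GM masking", {
  arr <- array(0L, c(10, 10, 4))
  arr[1:5, 1, 1] <- 1L   # 5 voxels
  arr[1:5, 2, 1] <- 1L   # + 5 = 10 voxels label 1
  arr[1:5, 3:5, 1] <- 2L # 15 voxels label 2
  lv <- label_volume(arr, 2, legend = c(a = 1, b = 2))
  def <- region_definition("temporal", "left", c(1, 2))
  mask <- combine_region_labels(lv, def)
  expect_equal(sum(mask), 25)
  # idempotent and commutative union
  expect_equal(mask, combine_region_labels(lv, region_definition(
    "temporal", "left", c(2, 1))))
  # GM mask halves the region
  gm <- array(FALSE, dim(arr)); gm[1:5, c(1, 3), 1] <- TRUE
  expect_equal(sum(combine_region_labels(lv, def, gm_mask = gm)), 10)
  # GMWM regions ignore the GM mask
  defw <- region_definition("thalamus", "left", c(1, 2))
  expect_equal(sum(combine_region_labels(lv, defw, gm_mask = gm)), 25)
  expect_error(combine_region_labels(lv, region_definition(
    "temporal", "left", 7)), "7")
})

test_that("TAC extraction averages voxels and reports volume in mL", {
  sch <- frame_schedule(3, 1, units = "min")
  img <- array(0, c(4, 4, 2, 3))
  img[1, 1, 1, ] <- 1
  img[2, 1, 1, ] <- 3
  mask <- array(FALSE, c(4, 4, 2)); mask[1:2, 1, 1] <- TRUE
  ex <- extract_region_tac(img, mask, 1.22, sch)
  expect_equal(ex$tac$values, rep(2, 3))
  expect_equal(ex$volume_ml, 2 * 1.22^3 / 1000)
  # 1000 voxels at 1.22 mm: 1.816 mL
  big <- array(TRUE, c(10, 10, 10))
  imgb <- array(1, c(10, 10, 10, 3))
  expect_equal(extract_region_tac(imgb, big, 1.22, sch)$volume_ml,
               1000 * 1.22^3 / 1000)
  expect_error(extract_region_tac(img, array(FALSE, c(4, 4, 2)), 1, sch),
               "empty mask")
})

test_that("phantom construction round-trips TACs, volumes and the GM shell", {
  cfg <- cohort_config(n_per_centre = c(Manchester = 1, Turku = 1), seed = 6)
  cohort <- generate_cohort(cfg)
  sch <- turku_schedule()
  ref <- ref_fixture(sch, amp = 30)
  ph <- generate_phantom_image(cohort$truth, "S001", sch, ref,
                               shell_p = 0.49)
  vs <- attr(ph$labels, "voxel_size_mm")
  gm_mask <- binarize_probability_map(ph$pmap)
  # the 0.49 shell is excluded from the thresholded mask
  expect_equal(sum(gm_mask), sum(ph$pmap == 1))
  for (key in c("thalamus.left", "frontal.right", "cerebellum_gm.left")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    def <- region_definition(parts[1], parts[2], ph$legend[[key]])
    mask <- combine_region_labels(ph$labels, def,
                                  gm_mask = if (def$tissue == "GM") gm_mask)
    ex <- extract_region_tac(ph$image4d, mask, vs, sch, label = key)
    expect_equal(ex$tac$values, ph$tacs[[key]]$values)   # exact round trip
    expect_equal(ex$volume_ml, sum(ph$labels == ph$legend[[key]]) *
                   vs^3 / 1000)
  }
  # left/right blobs are mirror-placed across the x midline
  lab <- array(ph$labels, dim(ph$labels))
  l <- which(lab == ph$legend[["thalamus.left"]], arr.ind = TRUE)
  r <- which(lab == ph$legend[["thalamus.right"]], arr.ind = TRUE)
  expect_equal(sort(dim(lab)[1] + 1 - r[, 1]), sort(l[, 1]))
  expect_equal(l[, 2:3], r[, 2:3])
  expect_error(generate_phantom_image(cohort$truth, "S001", sch, ref,
                                      grid_shape = c(6, 6, 4)), "too small")
})

test_that("voxelwise fit-then-average matches ROI-mean-TAC fitting on a clean phantom", {
  cfg <- cohort_config(n_per_centre = c(Manchester = 1, Turku = 1), seed = 12)
  cohort <- generate_cohort(cfg)
  sch <- turku_schedule()
  ref <- ref_fixture(sch, amp = 30)
  ph <- generate_phantom_image(cohort$truth, "S001", sch, ref,
                               regions = c("thalamus", "putamen"))
  mask <- array(ph$labels > 0 &
                  ph$labels != ph$legend[["cerebellum_gm.left"]] &
                  ph$labels != ph$legend[["cerebellum_gm.right"]],
                dim(ph$labels))
  maps <- fit_srtm_voxelwise(ph$image4d, ref, mask = mask, refine = TRUE)
  truth <- cohort$truth$params
  for (key in c("thalamus.left", "putamen.right")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    vox <- ph$labels == ph$legend[[key]]
    row <- truth[truth$subject_id == "S001" & truth$region == parts[1] &
                   truth$side == parts[2], ]
    # voxelwise average equals the truth (and hence the ROI-mean-TAC fit)
    expect_equal(mean(maps$DVR[vox]), row$DVR, tolerance = 1e-4)
    expect_equal(mean(maps$R1[vox]), row$R1, tolerance = 1e-4)
    roi_fit <- fit_srtm(extract_region_tac(ph$image4d, vox, 2, sch)$tac, ref)
    expect_equal(mean(maps$DVR[vox]), coef(roi_fit)[["DVR"]],
                 tolerance = 1e-4)
  }
  expect_true(all(is.na(maps$DVR[!mask])))
})
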