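# A capture with hand-placed square blobs on a zero background; fixed
# threshold keeps the geometry fully under our control.
blob_capture <- function(blobs, dim = c(200L, 200L), value = 1) {
  phase <- matrix(0, dim[1], dim[2])
  for (b in blobs) {
    phase[b$rows, b$cols] <- value
  }
  phase_capture(phase, "alive", "blob_test")
}
fixed_params <- function(...) {
  segmentation_params(threshold_method = "fixed", fixed_threshold = 0.5, ...)
}

test_that("detection finds one component per disjoint blob", {
  cap <- blob_capture(list(
    list(rows = 20:30, cols = 20:30),
    list(rows = 60:75, cols = 40:55),
    list(rows = 120:130, cols = 100:115),
    list(rows = 150:160, cols = 20:35),
    list(rows = 40:50, cols = 150:165)
  ))
  det <- detect_cells(cap, fixed_params())
  expect_identical(nrow(det), 5L)
  # centroid of the first square blob is its centre
  first <- det[det$row == 25, ]
  expect_identical(first$col, 25L)
  expect_identical(first$area_px, 121L)

  # a uniformly zero capture yields no detections, not an error
  empty <- phase_capture(matrix(0, 100, 100), "alive", "empty")
  expect_identical(nrow(detect_cells(empty, fixed_params())), 0L)
})

test_that("diagonal touching merges under 8-connectivity but not 4", {
  phase <- matrix(0, 100, 100)
  phase[40:50, 40:50] <- 1   # blob A
  phase[51:61, 51:61] <- 1   # blob B, touching only at the corner
  cap <- phase_capture(phase, "alive", "diag")
  expect_identical(nrow(detect_cells(cap, fixed_params())), 1L)
  expect_identical(
    nrow(detect_cells(cap, fixed_params(connectivity = 4L))), 2L
  )
})

test_that("area and border filters follow the strict cropping rules", {
  cap <- blob_capture(list(
    list(rows = 95:107, cols = 95:106),  # area 156: kept, mid-field
    list(rows = 50:56, cols = 50:56),    # area 49 (<= 80): discarded
    list(rows = 140:169, cols = 140:159) # area 600 (not < 600): discarded
  ))
  det <- detect_cells(cap, fixed_params())
  crops <- crop_cells(cap, det, fixed_params())
  expect_identical(nrow(crops), 1L)
  expect_identical(dim(crops$pixels[[1]]), c(66L, 66L))
  expect_identical(crops$area_px, 156L)
  d <- attr(crops, "discards")
  expect_setequal(d$reason, c("area_small", "area_large"))

  # centroid 10 px from the edge: the 66 px box crosses the border
  near_edge <- blob_capture(list(list(rows = 4:16, cols = 95:106)))
  det2 <- detect_cells(near_edge, fixed_params())
  crops2 <- crop_cells(near_edge, det2, fixed_params())
  expect_identical(nrow(crops2), 0L)
  expect_identical(attr(crops2, "discards")$reason, "border")

  # boundary case: area exactly 81 passes the strict > 80 bound
  cap81 <- blob_capture(list(list(rows = 100:108, cols = 100:108)))
  det81 <- detect_cells(cap81, fixed_params())
  expect_identical(det81$area_px, 81L)
  expect_identical(nrow(crop_cells(cap81, det81, fixed_params())), 1L)
})

test_that("every emitted crop equals the matching source window exactly", {
  g <- generate_capture(scene_spec(n_cells = 15, seed = 33,
                                   class_mix = c(alive = 0.4,
                                                 apoptosis = 0.3,
                                                 necroptosis = 0.3)))
  crops <- crop_cells(g$capture, detect_cells(g$capture))
  expect_gt(nrow(crops), 0L)
  for (i in seq_len(nrow(crops))) {
    r <- crops$row[i]; c <- crops$col[i]
    expect_identical(crops$pixels[[i]],
                     g$capture$phase[(r - 33):(r + 32), (c - 33):(c + 32)])
  }
})

test_that("crop counts equal the brute-force oracle on seeded captures", {
  counts_impl <- integer(0)
  counts_oracle <- integer(0)
  for (seed in 1:50) {
    g <- generate_capture(scene_spec(
      n_cells = 5 + (seed %% 12), seed = seed,
      image_shape = c(256L, 256L),
      class_mix = c(alive = 0.4, apoptosis = 0.3, necroptosis = 0.3),
      noise_sd_rad = 0.04
    ))
    params <- segmentation_params()
    det <- detect_cells(g$capture, params)
    crops <- crop_cells(g$capture, det, params)
    thr <- phasedeath:::segmentation_threshold(g$capture$phase, params)
    counts_impl <- c(counts_impl, nrow(crops))
    counts_oracle <- c(counts_oracle,
                       oracle_crop_count(g$capture$phase, thr))
  }
  expect_identical(counts_impl, counts_oracle)
  expect_gt(sum(counts_impl), 100L) # the comparison is not vacuous
})

test_that("widening the area window never loses crops", {
  g <- generate_capture(scene_spec(n_cells = 18, seed = 77,
                                   class_mix = c(alive = 0.4,
                                                 apoptosis = 0.3,
                                                 necroptosis = 0.3)))
  det <- detect_cells(g$capture)
  n_narrow <- nrow(crop_cells(g$capture, det,
                              segmentation_params(area_min_px = 150,
                                                  area_max_px = 400)))
  n_default <- nrow(crop_cells(g$capture, det, segmentation_params()))
  n_wide <- nrow(crop_cells(g$capture, det,
                            segmentation_params(area_min_px = 0,
                                                area_max_px = 1e6)))
  expect_lte(n_narrow, n_default)
  expect_lte(n_default, n_wide)
  expect_identical(n_wide, nrow(det) -
                     sum(attr(crop_cells(g$capture, det,
                                         segmentation_params(
                                           area_min_px = 0,
                                           area_max_px = 1e6
                                         )), "discards")$reason == "border"))
})
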