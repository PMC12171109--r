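test_that("Kirsch operator: constant image gives zero response", {
  expect_equal(kirsch_enhance(matrix(3.7, 16, 16)), matrix(0, 16, 16))
})

test_that("Kirsch operator: unit step edge responds with 15 on the edge column", {
  st <- matrix(0, 9, 9)
  st[, 6:9] <- 1
  resp <- kirsch_enhance(st)
  expect_equal(unique(resp[3:7, 5]), 15)
})

test_that("Kirsch operator matches the explicit 8-kernel oracle exactly", {
  for (s in c(1, 2, 3)) {
    set.seed(s)
    img <- matrix(runif(32 * 32), 32, 32)
    expect_identical(kirsch_enhance(img), oracle_kirsch(img))
  }
})

test_that("Li threshold separates a two-value image", {
  set.seed(1)
  tv <- matrix(0.2, 20, 20)
  tv[sample.int(400, 40)] <- 0.8   # 10% foreground
  th <- li_threshold(tv, segmentation_config(smoothing_scale = 1e-6))
  # on the original intensity scale the threshold lies between the modes
  thr_orig <- 0.2 + th$threshold * (0.8 - 0.2)
  expect_gt(thr_orig, 0.2)
  expect_lt(thr_orig, 0.8)
  expect_equal(sum(th$mask), 40)
})

test_that("Li iterative estimate is within one 8-bit level of exhaustive search", {
  for (s in 1:5) {
    im <- random_bimodal_image(64, seed = s)
    th <- li_threshold(im)
    ex <- oracle_li_exhaustive(th$smoothed)
    expect_lt(abs(th$threshold_raw - ex), 1 / 255)
  }
})

test_that("correction factor scales the pre-clamp threshold linearly", {
  im <- random_bimodal_image(32, seed = 7)
  t1 <- li_threshold(im, segmentation_config(correction_factor = 1))
  t2 <- li_threshold(im, segmentation_config(correction_factor = 2))
  expect_equal(t2$threshold_raw, t1$threshold_raw)
  expect_equal(t2$threshold, min(2 * t1$threshold_raw, 1))
})

test_that("raising the correction factor never increases the mask area", {
  im <- random_bimodal_image(32, seed = 3)
  areas <- vapply(c(0.5, 1, 1.5, 2), function(cf)
    sum(li_threshold(im, segmentation_config(correction_factor = cf))$mask),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("constant image yields an empty mask with a warning", {
  expect_warning(th <- li_threshold(matrix(5, 10, 10)), "constant")
  expect_true(is.na(th$threshold))
  expect_false(any(th$mask))
})

test_that("declumping splits two merged spots along the intensity valley", {
  g <- function(r0, c0) outer(1:21, 1:31, function(r, c)
    exp(-((r - r0)^2 + (c - c0)^2) / (2 * 2^2)))
  int <- g(11, 13) + g(11, 21)
  mask <- int > 0.05
  expect_equal(max(EBImage::bwlabel(mask)), 1)  # merged into one component
  labels <- declump(mask, int, segmentation_config(
    declump_min_distance_px = 5, declump_smooth_sigma_px = 1))
  expect_equal(max(labels), 2L)
  expect_true(labels[11, 13] != labels[11, 21])
  # the dividing line falls at the valley column between the peaks
  line_cols <- vapply(1:21, function(r) {
    row <- labels[r, ]
    if (all(row[13:21] > 0)) max(which(row == row[13])) else NA_integer_
  }, integer(1))
  expect_true(all(abs(stats::na.omit(line_cols) - 17) <= 2))
})

test_that("single blob with one maximum stays one object", {
  g <- outer(1:15, 1:15, function(r, c) exp(-((r - 8)^2 + (c - 8)^2) / 8))
  labels <- declump(g > 0.1, g, segmentation_config())
  expect_equal(max(labels), 1L)
})

test_that("hole filling closes enclosed background and grows the area", {
  ring <- matrix(FALSE, 15, 15)
  ring[4:12, 4:12] <- TRUE
  ring[6:10, 6:10] <- FALSE
  int <- ring * 1.0
  filled <- declump(ring, int, segmentation_config(fill_holes = TRUE))
  open <- declump(ring, int, segmentation_config(fill_holes = FALSE))
  expect_equal(sum(filled > 0), 81)          # full 9x9 square
  expect_equal(sum(open > 0), 81 - 25)
})

test_that("empty mask declumps to an empty label map", {
  labels <- declump(matrix(FALSE, 8, 8), matrix(0, 8, 8))
  expect_equal(max(labels), 0L)
  expect_equal(nrow(measure_objects(labels, matrix(0, 8, 8))), 0)
})

test_that("object measurement: intensity is the exact sum over the support", {
  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  labels <- matrix(0L, 10, 10)
  labels[2:4, 2:4] <- 1L
  labels[7:9, 6:9] <- 2L
  obj <- measure_objects(labels, img)
  expect_equal(obj$area_px, c(9L, 12L))
  expect_equal(obj$integrated_intensity[1], sum(img[2:4, 2:4]))
  expect_equal(obj$integrated_intensity[2], sum(img[7:9, 6:9]))
  # symmetric uniform object: centroid at the (0-based) geometric centre
  u <- matrix(0, 10, 10); u[2:4, 2:4] <- 1
  obj2 <- measure_objects(labels, u)
  expect_equal(obj2$centroid_row[1], 2)
  expect_equal(obj2$centroid_col[1], 2)
})

test_that("objects are assigned to cells by maximal overlap", {
  cells <- matrix(0L, 10, 20)
  cells[, 1:10] <- 3L
  cells[, 11:20] <- 7L
  obj_lab <- matrix(0L, 10, 20)
  obj_lab[5, 3:5] <- 1L           # fully inside cell 3
  obj_lab[5, 15:16] <- 2L         # fully inside cell 7
  obj_lab[8, 8:12] <- 3L          # straddles: 3 px in cell 3, 2 px in cell 7
  obj_lab[1, 1] <- 4L
  objects <- measure_objects(obj_lab, matrix(1, 10, 20))
  out <- assign_objects_to_cells(objects, obj_lab, cells)
  expect_equal(out$parent_cell_id[out$object_id == 1], 3L)
  expect_equal(out$parent_cell_id[out$object_id == 2], 7L)
  expect_equal(out$parent_cell_id[out$object_id == 3], 3L)  # 60/40 split
  # object overlapping no cell gets parent 0
  cells0 <- matrix(0L, 10, 20)
  cells0[, 1:5] <- 1L
  out0 <- assign_objects_to_cells(objects, obj_lab, cells0)
  expect_equal(out0$parent_cell_id[out0$object_id == 2], 0L)
})

test_that("noise-free blank image yields zero objects", {
  p <- image_sim_params(field_size_px = c(96, 96), n_cells = 0,
                        psf_sigma_px = 0, illum_gradient_amp = 0,
                        dark_offset = 0, read_noise_sd = 0,
                        shot_noise = FALSE, seed = 1)
  s <- simulate_field(p)
  expect_warning(seg <- segment_rna(s$image$channels$rna), "constant")
  expect_equal(nrow(seg$objects), 0)
})

test_that("segmentation labels are contiguous and respect the mask/fill bounds", {
  p <- image_sim_params(field_size_px = c(192, 192), n_cells = 2,
                        cell_radius_px = c(30, 40), seed = 6)
  s <- simulate_field(p)
  seg <- segment_rna(rescale01(s$image$channels$rna),
                     puncta_segmentation_config())
  labs <- sort(unique(as.integer(seg$labels[seg$labels > 0])))
  expect_identical(labs, seq_along(labs))
  th <- li_threshold(kirsch_enhance(rescale01(s$image$channels$rna)),
                     puncta_segmentation_config())
  expect_gte(sum(seg$labels > 0), sum(th$mask))  # hole filling only grows
})
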