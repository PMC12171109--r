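make_objects <- function(parent, area, intensity = area) {
  n <- length(parent)
  data.frame(field_id = rep(1L, n), object_id = seq_len(n),
             parent_cell_id = parent, area_px = area,
             integrated_intensity = intensity,
             centroid_row = rep(0, n), centroid_col = rep(0, n))
}

test_that("fraction of cellular area occupied follows its definition", {
  cells <- matrix(0L, 100, 100)
  cells[1:100, 1:100] <- 1L                      # one 10,000 px cell
  none <- make_objects(integer(0), integer(0))
  expect_equal(fraction_area_occupied(none, cells)$frac_area_occupied, 0)
  expect_equal(fraction_area_occupied(
    make_objects(1L, 10000L), cells)$frac_area_occupied, 1)
  expect_equal(fraction_area_occupied(
    make_objects(c(1L, 1L), c(200L, 50L)), cells)$frac_area_occupied, 0.025)
  expect_error(fraction_area_occupied(make_objects(9L, 10L), cells),
               "unknown parent")
})

test_that("ground-truth masks reproduce the simulator's occupied fraction exactly", {
  p <- image_sim_params(field_size_px = c(192, 192), n_cells = 2,
                        cell_radius_px = c(30, 40), seed = 12)
  s <- simulate_field(p)
  support <- s$clean$rna > 0
  # bypass segmentation: one truth object per cell, clipped to the cell
  objs <- do.call(rbind, lapply(s$truth$cells$cell_id, function(k) {
    make_objects(k, sum(support & s$truth$cell_labels == k))
  }))
  fa <- fraction_area_occupied(objs, s$truth$cell_labels)
  expect_identical(fa$frac_area_occupied, s$truth$cells$true_frac_occupied)
})

test_that("skewness matches closed forms and brute-force moments", {
  cells <- matrix(1L, 1, 4)
  img <- matrix(c(0, 0, 0, 1), 1, 4)
  expect_equal(cell_skewness(img, cells)$skewness,
               (1 - 2 * 0.25) / sqrt(0.25 * 0.75))   # Bernoulli closed form
  sym <- matrix(c(2, 2, 7, 7), 1, 4)
  expect_equal(cell_skewness(sym, cells)$skewness, 0)
  # affine invariance and brute-force agreement on random pixel sets
  set.seed(31)
  for (i in 1:5) {
    v <- rgamma(50, shape = 2)
    im <- matrix(v, 1, 50); cl <- matrix(1L, 1, 50)
    g1 <- cell_skewness(im, cl)$skewness
    expect_equal(g1, oracle_skewness(v), tolerance = 1e-12)
    expect_equal(cell_skewness(3.2 * im + 11, cl)$skewness, g1,
                 tolerance = 1e-12)
  }
  expect_warning(out <- cell_skewness(matrix(5, 1, 4), cells), "undefined")
  expect_true(is.na(out$skewness))
})

test_that("normalized cell intensity sums child object intensities over area", {
  cells <- matrix(1L, 20, 50)                     # 1,000 px cell
  expect_equal(normalized_cell_intensity(
    make_objects(integer(0), integer(0)), cells)$norm_intensity, 0)
  expect_equal(normalized_cell_intensity(
    make_objects(1L, 10L, 500), cells)$norm_intensity, 0.5)
  # linear in pixel intensities
  expect_equal(normalized_cell_intensity(
    make_objects(1L, 10L, 250), cells)$norm_intensity, 0.25)
})

test_that("one-sided comparison reproduces the pooled-t closed form", {
  r <- compare_conditions(c(1, 2, 3), c(2, 3, 4), direction = "less",
                          var_equal = TRUE)
  expect_equal(r$statistic, -sqrt(3) / sqrt(2), tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, stats::pt(-sqrt(3) / sqrt(2), 4), tolerance = 1e-9)
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3), direction = "less")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})

test_that("direction semantics are explicit: swapping groups flips the tail", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  p_less <- compare_conditions(a, b, "less")$p_value
  p_swap <- compare_conditions(b, a, "greater")$p_value
  expect_equal(p_less, p_swap)
})

test_that("granular condition scores lower area fraction and higher skewness", {
  # medians across seeds move in the published directions (small fields)
  meds <- sapply(c(2, 3, 4, 5, 6), function(s) {
    base <- list(field_size_px = c(192, 192), n_cells = 2,
                 cell_radius_px = c(30, 40), n_puncta_per_cell = 20)
    d <- quantify_field(do.call(image_sim_params, c(base, seed = s)))
    g <- quantify_field(do.call(image_sim_params,
                                c(base, granular = TRUE, seed = s)))
    c(d_fa = median(d$metrics$frac_area_occupied),
      g_fa = median(g$metrics$frac_area_occupied),
      d_sk = median(d$metrics$skewness),
      g_sk = median(g$metrics$skewness))
  })
  expect_lt(median(meds["g_fa", ]), median(meds["d_fa", ]))
  expect_gt(median(meds["g_sk", ]), median(meds["d_sk", ]))
})
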