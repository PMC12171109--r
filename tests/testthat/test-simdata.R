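# Small fields keep the suite fast; the generator's behaviour does not
# depend on field size.
small_params <- function(..., n_puncta_per_cell = 20, seed = 1) {
  image_sim_params(field_size_px = c(192, 192), n_cells = 2,
                   cell_radius_px = c(30, 40),
                   n_puncta_per_cell = n_puncta_per_cell, seed = seed, ...)
}

test_that("image generator is deterministic given params and seed", {
  a <- simulate_field(small_params(seed = 5))
  b <- simulate_field(small_params(seed = 5))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  f1 <- simulate_flatfield(small_params(seed = 5), n_fields = 3)
  f2 <- simulate_flatfield(small_params(seed = 5), n_fields = 3)
  expect_identical(f1$fields, f2$fields)
})

test_that("noiseless RNA channel support equals the planted footprint", {
  p <- small_params(psf_sigma_px = 0, illum_gradient_amp = 0,
                    dark_offset = 0, read_noise_sd = 0, shot_noise = FALSE,
                    seed = 3)
  s <- simulate_field(p)
  expect_identical(s$image$channels$rna > 0, s$clean$rna > 0)
  # every punctum lies inside its parent cell mask
  idx <- cbind(s$truth$puncta$row + 1, s$truth$puncta$col + 1)
  expect_true(all(s$truth$cell_labels[idx] == s$truth$puncta$cell_id))
  expect_true(all(s$truth$cells$true_frac_occupied >= 0 &
                    s$truth$cells$true_frac_occupied <= 1))
})

test_that("clustering the same punctum budget occupies strictly less area", {
  for (s in c(2, 4, 6)) {
    d <- simulate_field(small_params(seed = s))
    g <- simulate_field(small_params(granular = TRUE, seed = s))
    expect_lt(median(g$truth$cells$true_frac_occupied),
              median(d$truth$cells$true_frac_occupied))
  }
})

test_that("zero cells or zero puncta give valid empty truth, not errors", {
  e <- simulate_field(image_sim_params(field_size_px = c(128, 128),
                                       n_cells = 0, seed = 1))
  expect_equal(nrow(e$truth$cells), 0)
  expect_equal(nrow(e$truth$puncta), 0)
  e2 <- simulate_field(small_params(n_puncta_per_cell = 0, seed = 1))
  expect_equal(nrow(e2$truth$puncta), 0)
  expect_equal(e2$truth$cells$true_frac_occupied, c(0, 0))
})

test_that("flat-field stack: flat illumination and zero noise give constant fields", {
  p <- small_params(illum_gradient_amp = 0, read_noise_sd = 0,
                    shot_noise = FALSE, seed = 1)
  ff <- simulate_flatfield(p, n_fields = 3, level = 500)
  for (f in ff$fields) expect_equal(unique(as.numeric(f)), 500 + p$dark_offset)
  expect_equal(ff$dark[1, 1], p$dark_offset)
})

test_that("pure exponential counts follow the closed form exactly", {
  p <- count_sim_params("X", timepoints_h = c(0, 5, 10), n_replicates = 1,
                        amplitude = 1000, h_fast = 5, h_slow = 5, f = 1,
                        lognormal_noise_sd = 0, early_window = c(0, 5),
                        late_window = c(5, 10), seed = 1)
  sim <- simulate_decay_counts(p)
  x <- sim$counts[sim$counts$transcript == "X", ]
  expect_equal(x$count[order(x$timepoint_h)], 1000 * c(1, 0.5, 0.25))
})

test_that("two-population model value at 5 h matches direct evaluation", {
  p <- count_sim_params("X", timepoints_h = c(0, 2, 5, 8, 24),
                        n_replicates = 1, amplitude = 1, h_fast = 1.5,
                        h_slow = 12, f = 0.8, lognormal_noise_sd = 0, seed = 1)
  sim <- simulate_decay_counts(p)
  x <- sim$counts[sim$counts$transcript == "X", ]
  ratio <- x$count[x$timepoint_h == 5] / x$count[x$timepoint_h == 0]
  expect_equal(ratio, 0.2292008, tolerance = 1e-6)
})

test_that("count table has one row per transcript, timepoint and replicate", {
  p <- count_sim_params(c("A", "B"), timepoints_h = c(0, 2, 5, 8, 24),
                        n_replicates = 3, seed = 9)
  sim <- simulate_decay_counts(p)
  expect_equal(nrow(sim$counts), (2 + 1) * 5 * 3)  # + GAPDH reference rows
  key <- with(sim$counts, paste(transcript, timepoint_h, replicate))
  expect_false(anyDuplicated(key) > 0)
  # seeded reproducibility
  expect_identical(simulate_decay_counts(p)$counts, sim$counts)
})

test_that("invalid decay parameters are rejected", {
  expect_error(count_sim_params("X", h_fast = -1), "h_fast")
  expect_error(count_sim_params("X", h_fast = 10, h_slow = 2), "h_fast")
  expect_error(count_sim_params("X", f = 1.2))
})

test_that("labeling generator: zero rise gives constant labeled counts", {
  p <- count_sim_params("MT-ND1", timepoints_h = c(0, 2, 5), n_replicates = 2,
                        lognormal_noise_sd = 0, early_window = c(0, 2, 5),
                        late_window = c(0, 2, 5), seed = 2)
  sim <- simulate_labeling_counts(p, rise_amplitude = 0, labeled_baseline = 50)
  lab <- sim$counts[sim$counts$fraction == "labeled" &
                      sim$counts$transcript == "MT-ND1", ]
  expect_equal(unique(lab$count), 50)
  # noiseless unlabeled counts at t = 0 equal total pre-release abundance
  unl <- sim$counts[sim$counts$fraction == "unlabeled" &
                      sim$counts$transcript == "MT-ND1", ]
  expect_equal(unique(unl$count[unl$timepoint_h == 0]), p$amplitude[1])
  # seeded reproducibility
  expect_identical(simulate_labeling_counts(p, rise_amplitude = 0,
                                            labeled_baseline = 50)$counts,
                   sim$counts)
})
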