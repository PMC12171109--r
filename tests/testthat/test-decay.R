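tidy_counts <- function(transcript, timepoint, replicate, count,
                        condition = "EtBr") {
  data.frame(transcript = transcript, condition = condition,
             timepoint_h = timepoint, replicate = replicate, count = count,
             fraction = "total",
             sample_id = paste(condition, timepoint, replicate, sep = "_"))
}

test_that("reference normalization divides by the per-sample reference count", {
  tab <- rbind(tidy_counts("A", c(0, 5), 1, c(300, 100)),
               tidy_counts("GAPDH", c(0, 5), 1, c(150, 100)))
  out <- normalize_to_reference(tab, "GAPDH")
  expect_equal(out$norm_count[out$transcript == "A"], c(2, 1))
  # reference all ones leaves counts unchanged
  tab1 <- rbind(tidy_counts("A", 0:2, 1, c(5, 4, 3)),
                tidy_counts("R", 0:2, 1, c(1, 1, 1)))
  expect_equal(normalize_to_reference(tab1, "R")$norm_count[1:3], c(5, 4, 3))
  # scale invariance per sample
  tab2 <- tab
  tab2$count <- tab2$count * ifelse(tab2$timepoint_h == 0, 7, 3)
  expect_equal(normalize_to_reference(tab2, "GAPDH")$norm_count,
               out$norm_count)
  # zero or missing reference is an error naming the sample
  tab3 <- tab; tab3$count[tab3$transcript == "GAPDH" & tab3$timepoint_h == 5] <- 0
  expect_error(normalize_to_reference(tab3, "GAPDH"), "EtBr_5_1")
})

test_that("window fit recovers an exact exponential half-life analytically", {
  for (w in list(c(0, 2, 5), c(5, 8, 24))) {
    y <- 2^(-w / 5)
    fit <- fit_window_halflife(w, y, anchor_time = w[1])
    expect_equal(fit$t_half, 5, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("window fit matches a hand OLS oracle and the half-life identity", {
  t <- c(0, 2, 5); y <- c(1.0, 0.8, 0.4)
  fit <- fit_window_halflife(t, y, 0)
  orc <- oracle_log10_ols(t, y, 0)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-12)
  expect_equal(fit$t_half, orc$t_half, tolerance = 1e-12)
  expect_equal(fit$t_half * fit$slope, -log10(2), tolerance = 1e-12)
})

test_that("increasing series yields a negative half-life, reported as-is", {
  fit <- fit_window_halflife(c(0, 2, 5), c(1, 1.5, 2.5), 0)
  expect_lt(fit$t_half, 0)
})

test_that("window fit validates its inputs", {
  expect_error(fit_window_halflife(c(0, 2, 5), c(1, 0, 0.5), 0),
               "non-positive")
  expect_error(fit_window_halflife(c(0, 2, 5), c(1, 1, 1), 3), "anchor")
})

test_that("noiseless single exponential is classified one-state", {
  p <- count_sim_params("X", n_replicates = 1, h_fast = 4, h_slow = 4, f = 1,
                        lognormal_noise_sd = 0, seed = 1)
  nt <- normalize_to_reference(simulate_decay_counts(p)$counts, "GAPDH")
  res <- two_phase_halflives(nt)
  expect_equal(res$classification, "one-state")
  expect_equal(res$t_early_half, 4, tolerance = 1e-9)
  expect_equal(res$t_late_half, 4, tolerance = 1e-9)
  expect_false(res$fallback_applied)
})

test_that("published half-life table classifies the expected two-state sets", {
  ref <- reference_halflives()
  cls <- classify_decay(ref$t_early_half, ref$t_late_half)
  two_etbr <- ref$transcript[cls == "two-state" & ref$condition == "EtBr"]
  two_imt <- ref$transcript[cls == "two-state" & ref$condition == "IMT1B"]
  expect_true(all(c("MT-ND5", "MT-ND6") %in% two_etbr))
  expect_true(all(c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND5", "MT-ND6")
                  %in% two_imt))
  expect_equal(cls[ref$transcript == "c-MYC"], c("increasing", "increasing"))
  # Table ratios: MT-ND6 EtBr 34.40/1.84 ~ 18.7 two-state,
  # MT-CO1 EtBr 4.92/2.40 ~ 2.05 one-state
  expect_false("MT-CO1" %in% two_etbr)
})

test_that("estimator reproduces a published half-life table from synthetic counts", {
  cts <- synthetic_counts_from_halflives()
  res <- two_phase_halflives(normalize_to_reference(cts, "GAPDH"))
  ref <- reference_halflives()
  m <- merge(res, ref, by = c("transcript", "condition"))
  expect_equal(nrow(m), 30)
  expect_lt(max(abs(m$t_early_half.x - m$t_early_half.y)), 0.05)
  expect_lt(max(abs(m$t_late_half.x - m$t_late_half.y)), 0.05)
  expect_identical(m$fallback_applied, m$early_two_point_fallback)
})

test_that("two-phase half-lives are recovered from noisy replicates", {
  p <- count_sim_params(paste0("T", 1:20), h_fast = 1.5, h_slow = 12,
                        f = 0.8, lognormal_noise_sd = 0.1, n_replicates = 3,
                        seed = 21)
  sim <- simulate_decay_counts(p)
  res <- two_phase_halflives(normalize_to_reference(sim$counts, "GAPDH"))
  m <- merge(res, sim$truth, by = "transcript")
  rel_early <- abs(m$t_early_half - m$t_early_half_true) / m$t_early_half_true
  rel_late <- abs(m$t_late_half - m$t_late_half_true) / m$t_late_half_true
  expect_lt(median(rel_early), 0.15)
  expect_lt(median(rel_late), 0.15)
})

test_that("early fit is invariant to the overall scale of the series", {
  tab <- rbind(tidy_counts("A", c(0, 2, 5, 8, 24), 1,
                           1000 * c(1, 0.7, 0.35, 0.2, 0.05)),
               tidy_counts("GAPDH", c(0, 2, 5, 8, 24), 1, rep(1, 5)))
  tab2 <- tab; tab2$count[tab2$transcript == "A"] <-
    tab2$count[tab2$transcript == "A"] * 1e3
  r1 <- two_phase_halflives(normalize_to_reference(tab, "GAPDH"))
  r2 <- two_phase_halflives(normalize_to_reference(tab2, "GAPDH"))
  expect_equal(r1$t_early_half, r2$t_early_half)
  expect_equal(r1$t_late_half, r2$t_late_half)
})

test_that("log fold change handles ratios and unmatched transcripts", {
  tab <- rbind(tidy_counts("A", 0, 1:2, c(100, 100), condition = "treated"),
               tidy_counts("A", 0, 1:2, c(400, 400), condition = "control"),
               tidy_counts("B", 0, 1:2, c(10, 10), condition = "control"))
  tab$norm_count <- tab$count
  expect_warning(fc <- log_fold_change(tab, "treated", "control"), "B")
  expect_equal(fc$log2_fc[fc$transcript == "A"], -2)
  same <- tab[tab$transcript == "A", ]
  expect_equal(log_fold_change(same, "treated", "treated")$log2_fc, 0)
})

test_that("Pearson correlation and r-squared behave as defined", {
  x <- c(1, 2, 3); y <- 2 * x + 1
  expect_equal(pearson_r2(x, y)$r2, 1)
  r <- pearson_r2(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5)
  expect_equal(r$r2, 0.25)
  # invariant to affine transforms of either vector
  expect_equal(pearson_r2(5 * x - 2, c(1, 3, 2))$r2, 0.25)
  expect_error(pearson_r2(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_r2(c(1, 2), c(1, 2)))
})
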