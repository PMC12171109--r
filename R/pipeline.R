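#' Run the imaging arm on one simulated field
#'
#' Convenience composition used by the analysis scripts and tests: simulate a
#' field, simulate and average matching empty-well flat-fields, flat-field
#' correct the RNA channel, segment RNA objects, assign them to the
#' ground-truth cell masks, and compute the per-cell metrics.
#'
#' @param params an [image_sim_params()] object.
#' @param cfg a [segmentation_config()].
#' @param n_flat number of simulated flat-fields to average (0 disables
#'   correction and segments the raw channel).
#' @param field_id field identifier carried through the tables.
#' @return list: `metrics` (per-cell data.frame), `objects`, `labels`,
#'   `truth`, `corrected_rna` (matrix the metrics were measured on).
#' @export
quantify_field <- function(params, cfg = puncta_segmentation_config(),
                           n_flat = 10L, field_id = 1L) {
  sim <- simulate_field(params)
  rna <- sim$image$channels$rna
  if (n_flat > 0) {
    ff <- simulate_flatfield(params, n_fields = n_flat)
    flat <- average_flatfield(ff$fields)
    rna <- flatfield_correct(rna, flat, dark = params$dark_offset)
  }
  seg <- segment_rna(rna, cfg, cells = sim$truth$cell_labels,
                     field_id = field_id)
  met <- cell_metrics(seg$objects, sim$truth$cell_labels, rna,
                      condition = params$condition, field_id = field_id)
  list(metrics = met, objects = seg$objects, labels = seg$labels,
       truth = sim$truth, corrected_rna = rna)
}

#' Quantify a pair of conditions over several fields and compare them
#'
#' Simulates `n_fields` fields per condition (seeds `seed_base + 1..n` for
#' the control and `seed_base + 101..` for the treated condition), runs the
#' full imaging arm on each, pools the per-cell metrics, and performs the
#' one-sided tests in the published directions: fraction of cellular area
#' occupied decreases, skewness increases, in the granular/treated condition.
#'
#' @param control_params,treated_params [image_sim_params()] templates; their
#'   `seed` is overridden per field.
#' @param n_fields fields per condition.
#' @param seed_base base seed.
#' @param cfg a [segmentation_config()].
#' @return list: `metrics` (pooled per-cell table), `comparisons`
#'   (rbind of the two `comparison_result` rows).
#' @export
quantify_condition_pair <- function(control_params, treated_params,
                                    n_fields = 5L, seed_base = 0L,
                                    cfg = puncta_segmentation_config()) {
  run_all <- function(template, seeds) {
    do.call(rbind, lapply(seq_along(seeds), function(i) {
      p <- template
      p$seed <- seeds[i]
      q <- quantify_field(p, cfg, field_id = i)
      q$metrics
    }))
  }
  m_ctrl <- run_all(control_params, seed_base + seq_len(n_fields))
  m_trt <- run_all(treated_params, seed_base + 100L + seq_len(n_fields))
  metrics <- rbind(m_ctrl, m_trt)
  comparisons <- rbind(
    compare_conditions(m_trt$frac_area_occupied, m_ctrl$frac_area_occupied,
                       direction = "less", metric = "frac_area_occupied"),
    compare_conditions(m_trt$skewness, m_ctrl$skewness,
                       direction = "greater", metric = "skewness"))
  list(metrics = metrics, comparisons = comparisons)
}

#' Match detected objects to planted puncta and score detection
#'
#' Greedy one-to-one matching of object centroids to ground-truth punctum
#' coordinates in order of increasing distance, accepting pairs within
#' `match_radius` px. Recall = matched puncta / planted puncta; precision =
#' matched objects / detected objects. Clustered puncta closer than the
#' match radius can legitimately merge into one object; callers evaluating
#' detection use diffuse fields.
#'
#' @param objects object table (centroids 0-based).
#' @param truth_puncta data.frame with 0-based `row`, `col` columns.
#' @param match_radius maximum centroid distance in px (default 2).
#' @return list: recall, precision, n_matched, n_truth, n_detected.
#' @export
detection_performance <- function(objects, truth_puncta, match_radius = 2) {
  n_t <- nrow(truth_puncta); n_d <- nrow(objects)
  if (n_t == 0 || n_d == 0)
    return(list(recall = if (n_t == 0) 1 else 0,
                precision = if (n_d == 0) 1 else 0,
                n_matched = 0L, n_truth = n_t, n_detected = n_d))
  d <- outer(objects$centroid_row, truth_puncta$row, "-")^2 +
    outer(objects$centroid_col, truth_puncta$col, "-")^2
  pairs <- which(d <= match_radius^2, arr.ind = TRUE)
  if (nrow(pairs) == 0)
    return(list(recall = 0, precision = 0, n_matched = 0L,
                n_truth = n_t, n_detected = n_d))
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_o <- logical(n_d); used_t <- logical(n_t)
  n_match <- 0L
  for (i in seq_len(nrow(pairs))) {
    o <- pairs[i, 1]; t <- pairs[i, 2]
    if (!used_o[o] && !used_t[t]) {
      used_o[o] <- TRUE; used_t[t] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(recall = n_match / n_t, precision = n_match / n_d,
       n_matched = n_match, n_truth = n_t, n_detected = n_d)
}
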