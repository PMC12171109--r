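#' Normalize a count table to a reference transcript
#'
#' Divides every count by the count of the reference transcript measured in
#' the same sample (and same fraction). Normalization is therefore invariant
#' to per-sample scale factors. The reference used is recorded in the
#' `reference` attribute.
#'
#' @param table tidy count data.frame (columns transcript, sample_id,
#'   condition, timepoint_h, replicate, fraction, count).
#' @param reference transcript name to normalize to (e.g. "GAPDH", "c-MYC",
#'   or a spike-in).
#' @return the table with an added `norm_count` column.
#' @export
normalize_to_reference <- function(table, reference) {
  req <- c("transcript", "sample_id", "count")
  stopifnot(all(req %in% names(table)))
  ref_rows <- table[table$transcript == reference, , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$fraction %||% "", sep = "\r")
  ref_val <- ref_rows$count[match(key(table), key(ref_rows))]
  bad <- is.na(ref_val) | ref_val <= 0
  if (any(bad)) {
    stop("reference '", reference, "' absent or non-positive in sample(s): ",
         paste(utils::head(unique(table$sample_id[bad]), 5), collapse = ", "))
  }
  table$norm_count <- table$count / ref_val
  attr(table, "reference") <- reference
  table
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-linear half-life fit over one time window
#'
#' Expresses the series relative to its value at `anchor_time` (the anchor is
#' "100%"), fits ordinary least squares of log10(relative) on time with a
#' free intercept, and converts the slope to a half-life via
#' `t_half = (log10(0.5) - log10(1)) / slope = -log10(2) / slope`. A positive
#' slope yields a negative half-life (reported as-is: the series increased);
#' a zero slope yields +Inf.
#'
#' @param time_h numeric times (h) of the window, anchor included.
#' @param value positive normalized counts at those times (replicate means).
#' @param anchor_time the timepoint set to 100% (must be in `time_h`).
#' @return list: slope (log10 units/h), t_half (h), r_squared, n.
#' @export
fit_window_halflife <- function(time_h, value, anchor_time = time_h[1]) {
  stopifnot(length(time_h) == length(value), length(time_h) >= 2)
  if (!anchor_time %in% time_h)
    stop("anchor time ", anchor_time, " not among the window timepoints")
  if (any(value <= 0))
    stop("non-positive values at timepoint(s) ",
         paste(time_h[value <= 0], collapse = ", "),
         "; log-linear fit undefined")
  rel <- value / value[match(anchor_time, time_h)]
  fit <- stats::lm(log10(rel) ~ time_h)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((log10(rel) - mean(log10(rel)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  t_half <- if (slope == 0) Inf else -log10(2) / slope
  list(slope = slope, t_half = t_half, r_squared = r2, n = length(time_h))
}

#' Two-window half-life estimation and decay classification
#'
#' For every transcript (and condition) in a reference-normalized count
#' table: average the replicates per timepoint, fit the early window
#' (anchored at its first timepoint set to 100%) and the late window
#' (anchored likewise), and classify the decay mode. A two-point fallback
#' reproduces how increasing interior timepoints were handled in the
#' published table: when the 3-point early half-life is negative or an
#' interior early timepoint lies above the anchor, the window is refit on its
#' first and last timepoints only, and that fit is adopted if its half-life
#' is positive (`fallback_applied = TRUE`).
#'
#' Classification: "increasing" if the early half-life stays negative;
#' "unstable" if the early half-life is positive but the late one negative;
#' "two-state" if both are positive and `t_late / t_early >= ratio_threshold`
#' (biphasic: a fast-decaying and a stabilized population); otherwise
#' "one-state". The ratio threshold is a package choice (default 4), not a
#' published constant.
#'
#' @param table output of [normalize_to_reference()] (needs `norm_count`).
#' @param early_window,late_window timepoints of the two windows; the first
#'   element of each is the anchor.
#' @param ratio_threshold minimum late/early half-life ratio for a
#'   "two-state" call.
#' @return data.frame, one row per transcript x condition: early/late slope,
#'   half-life and R^2, fallback_applied, classification.
#' @export
two_phase_halflives <- function(table,
                                early_window = c(0, 2, 5),
                                late_window = c(5, 8, 24),
                                ratio_threshold = 4) {
  stopifnot("norm_count" %in% names(table), ratio_threshold > 0)
  tps <- sort(unique(table$timepoint_h))
  missing_tp <- setdiff(c(early_window, late_window), tps)
  if (length(missing_tp) > 0)
    stop("table lacks required timepoint(s): ",
         paste(missing_tp, collapse = ", "))
  ref_name <- attr(table, "reference") %||% ""
  combos <- unique(table[table$transcript != ref_name,
                         c("transcript", "condition")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- table[table$transcript == combos$transcript[i] &
                   table$condition == combos$condition[i], ]
    means <- tapply(sub$norm_count, sub$timepoint_h, mean)
    tp <- as.numeric(names(means))
    get <- function(w) as.numeric(means[match(w, tp)])

    early <- fit_window_halflife(early_window, get(early_window),
                                 early_window[1])
    fallback <- FALSE
    interior <- setdiff(early_window, range(early_window))
    rel_e <- get(early_window) / get(early_window[1])
    if (early$t_half < 0 || any(rel_e[match(interior, early_window)] > 1)) {
      two_pt <- range(early_window)
      refit <- fit_window_halflife(two_pt, get(two_pt), two_pt[1])
      if (refit$t_half > 0) {
        early <- refit
        fallback <- TRUE
      }
    }
    late <- fit_window_halflife(late_window, get(late_window), late_window[1])

    classification <- if (early$t_half < 0) "increasing"
      else if (late$t_half < 0) "unstable"
      else if (late$t_half / early$t_half >= ratio_threshold) "two-state"
      else "one-state"
    data.frame(transcript = combos$transcript[i],
               condition = combos$condition[i],
               early_slope = early$slope, t_early_half = early$t_half,
               early_r2 = early$r_squared,
               late_slope = late$slope, t_late_half = late$t_half,
               late_r2 = late$r_squared,
               fallback_applied = fallback,
               classification = classification)
  })
  out <- do.call(rbind, res)
  attr(out, "windows") <- list(early = early_window, late = late_window,
                               ratio_threshold = ratio_threshold)
  out
}

#' Classify decay mode from a pair of half-lives
#'
#' Same rule as [two_phase_halflives()] applied directly to tabulated
#' early/late half-lives (e.g. a published table).
#'
#' @param t_early,t_late half-lives in hours (negative = increasing).
#' @param ratio_threshold minimum late/early ratio for "two-state".
#' @return character vector of classifications.
#' @export
classify_decay <- function(t_early, t_late, ratio_threshold = 4) {
  mapply(function(e, l) {
    if (e < 0) "increasing"
    else if (l < 0) "unstable"
    else if (l / e >= ratio_threshold) "two-state"
    else "one-state"
  }, t_early, t_late)
}

#' Per-transcript log2 fold change between conditions
#'
#' Replicate means of the normalized counts are taken first within each
#' condition; the change is `log2(treated / control)`. Transcripts missing
#' from either condition are dropped with a warning.
#'
#' @param table output of [normalize_to_reference()].
#' @param treated,control condition labels to compare.
#' @return data.frame: transcript, log2_fc.
#' @export
log_fold_change <- function(table, treated, control) {
  stopifnot("norm_count" %in% names(table))
  mean_by <- function(cond) {
    sub <- table[table$condition == cond, ]
    tapply(sub$norm_count, sub$transcript, mean)
  }
  mt <- mean_by(treated); mc <- mean_by(control)
  common <- intersect(names(mt), names(mc))
  lost <- setdiff(union(names(mt), names(mc)), common)
  if (length(lost) > 0)
    warning("transcript(s) missing in one condition, dropped: ",
            paste(lost, collapse = ", "))
  if (any(mc[common] <= 0))
    stop("zero/negative control mean for: ",
         paste(common[mc[common] <= 0], collapse = ", "))
  data.frame(transcript = common,
             log2_fc = as.numeric(log2(mt[common] / mc[common])),
             row.names = NULL)
}

#' Pearson correlation with r-squared
#'
#' @param x,y equal-length numeric vectors (n >= 3, no missing values).
#' @param labels optional character pair naming the two vectors.
#' @return list of class `correlation_result`: n, r, r2, labels.
#' @export
pearson_r2 <- function(x, y, labels = c("x", "y")) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input; correlation undefined")
  r <- stats::cor(x, y)
  structure(list(n = length(x), r = r, r2 = r * r, labels = labels),
            class = "correlation_result")
}
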