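#' Transient-transcription metagene over recovery time
#'
#' Summarises how fast transcription restarts after release from inhibition:
#' at each recovery timepoint, the 4sU-labeled count of every transcript in
#' the panel is divided by the labeled reference (e.g. labeled GAPDH), the
#' ratios are averaged over transcripts within each replicate (mean of
#' ratios), and the replicate means are then averaged. The ribbon half-width
#' is a 95% confidence interval from the t-distribution across replicate
#' means (df = n_replicates - 1).
#'
#' @param table tidy labeling count table (fraction column with "labeled"
#'   rows; columns as in [simulate_labeling_counts()]).
#' @param reference labeled reference transcript name.
#' @param transcripts panel to average over (default the 13 mt-mRNAs).
#' @param conf_level confidence level of the ribbon (default 0.95).
#' @return list: `series` (data.frame timepoint_h, mean_rel, ci_halfwidth,
#'   n_replicates, n_transcripts) and `replicate_means` (data.frame
#'   timepoint_h, replicate, rel).
#' @export
transient_metagene <- function(table, reference,
                               transcripts = mt_transcripts(),
                               conf_level = 0.95) {
  lab <- table[table$fraction == "labeled", ]
  if (nrow(lab) == 0) stop("table has no labeled-fraction rows")
  ref <- lab[lab$transcript == reference, ]
  panel <- lab[lab$transcript %in% transcripts, ]
  missing_t <- setdiff(transcripts, unique(panel$transcript))
  if (length(missing_t) > 0)
    warning("panel transcript(s) absent from table: ",
            paste(missing_t, collapse = ", "))

  key <- function(d) paste(d$timepoint_h, d$replicate)
  ref_val <- ref$count[match(key(panel), key(ref))]
  if (anyNA(ref_val))
    stop("labeled reference '", reference, "' missing at timepoint(s): ",
         paste(unique(panel$timepoint_h[is.na(ref_val)]), collapse = ", "))
  panel$rel <- panel$count / ref_val

  rep_means <- stats::aggregate(rel ~ timepoint_h + replicate, panel, mean)
  alpha <- 1 - conf_level
  series <- do.call(rbind, lapply(split(rep_means, rep_means$timepoint_h),
    function(d) {
      n <- nrow(d)
      hw <- if (n > 1)
        stats::qt(1 - alpha / 2, n - 1) * stats::sd(d$rel) / sqrt(n) else 0
      data.frame(timepoint_h = d$timepoint_h[1], mean_rel = mean(d$rel),
                 ci_halfwidth = hw, n_replicates = n,
                 n_transcripts = length(unique(panel$transcript)))
    }))
  rownames(series) <- NULL
  list(series = series, replicate_means = rep_means)
}

#' Spike-in-normalized decay of the unlabeled (preexisting) RNA fraction
#'
#' Normalizes the unlabeled-fraction counts to the unlabeled spike-in
#' measured in the same sample and averages replicates per transcript and
#' recovery timepoint. The log10 transform is a display choice and is left
#' to the caller.
#'
#' @param table tidy labeling count table.
#' @param spikein unlabeled spike-in transcript name (default "ERCC-00048").
#' @return data.frame: transcript, timepoint_h, mean_norm, n_replicates.
#' @export
unlabeled_decay <- function(table, spikein = "ERCC-00048") {
  unl <- table[table$fraction == "unlabeled", ]
  if (nrow(unl) == 0) stop("table has no unlabeled-fraction rows")
  sp <- unl[unl$transcript == spikein, ]
  rest <- unl[unl$transcript != spikein, ]
  key <- function(d) paste(d$timepoint_h, d$replicate)
  sp_val <- sp$count[match(key(rest), key(sp))]
  if (anyNA(sp_val) || any(sp_val <= 0))
    stop("spike-in '", spikein, "' missing or non-positive in some samples")
  rest$norm <- rest$count / sp_val
  out <- stats::aggregate(norm ~ transcript + timepoint_h, rest,
                          function(v) c(mean = mean(v), n = length(v)))
  data.frame(transcript = out$transcript, timepoint_h = out$timepoint_h,
             mean_norm = out$norm[, "mean"],
             n_replicates = as.integer(out$norm[, "n"]))
}
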