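#' Fraction of cellular area occupied by RNA objects
#'
#' For every cell in the label map, the summed area of its assigned RNA
#' objects divided by the cell area. Cells with no assigned objects get 0
#' (they are retained: dropping them would bias a treated condition in which
#' signal concentrates into few objects). A low fraction indicates a granular
#' spatial state, a high fraction a diffuse one.
#'
#' @param objects object table with `parent_cell_id` filled in.
#' @param cell_labels integer cell label matrix.
#' @return data.frame: cell_id, cell_area_px, rna_area_px, frac_area_occupied.
#' @export
fraction_area_occupied <- function(objects, cell_labels) {
  n_cells <- max(0L, max(cell_labels))
  if (n_cells == 0)
    return(data.frame(cell_id = integer(0), cell_area_px = integer(0),
                      rna_area_px = numeric(0), frac_area_occupied = numeric(0)))
  area <- tabulate(cell_labels[cell_labels > 0], nbins = n_cells)
  parent <- objects$parent_cell_id
  if (any(parent > n_cells))
    stop("object table references unknown parent cell id(s): ",
         paste(unique(parent[parent > n_cells]), collapse = ", "))
  rna <- numeric(n_cells)
  assigned <- parent > 0
  if (any(assigned)) {
    s <- tapply(objects$area_px[assigned], parent[assigned], sum)
    rna[as.integer(names(s))] <- as.numeric(s)
  }
  data.frame(cell_id = seq_len(n_cells), cell_area_px = area,
             rna_area_px = rna, frac_area_occupied = rna / area)
}

#' Per-cell skewness of the RNA signal distribution
#'
#' Population skewness `g1 = m3 / m2^(3/2)` (central moments over all pixels
#' inside each cell mask) of the corrected, z-projected RNA channel. Signal
#' concentrated into bright granules produces a long right tail and hence a
#' larger skewness. Cells with zero pixel variance yield NA with a warning.
#'
#' @param image 2-D matrix, corrected sum projection of the RNA channel.
#' @param cell_labels integer cell label matrix.
#' @return data.frame: cell_id, skewness.
#' @export
cell_skewness <- function(image, cell_labels) {
  stopifnot(identical(dim(image), dim(cell_labels)))
  n_cells <- max(0L, max(cell_labels))
  sk <- rep(NA_real_, n_cells)
  for (k in seq_len(n_cells)) {
    v <- image[cell_labels == k]
    if (length(v) == 0) next
    m <- mean(v)
    m2 <- mean((v - m)^2)
    if (m2 == 0) {
      warning("cell ", k, ": constant pixel values, skewness undefined")
      next
    }
    sk[k] <- mean((v - m)^3) / m2^1.5
  }
  data.frame(cell_id = seq_len(n_cells), skewness = sk)
}

#' Normalized per-cell RNA intensity
#'
#' Sum of the integrated intensities of a cell's RNA objects (measured on the
#' original RNA channel) divided by the cell area.
#'
#' @inheritParams fraction_area_occupied
#' @return data.frame: cell_id, norm_intensity.
#' @export
normalized_cell_intensity <- function(objects, cell_labels) {
  n_cells <- max(0L, max(cell_labels))
  if (n_cells == 0)
    return(data.frame(cell_id = integer(0), norm_intensity = numeric(0)))
  area <- tabulate(cell_labels[cell_labels > 0], nbins = n_cells)
  tot <- numeric(n_cells)
  assigned <- objects$parent_cell_id > 0
  if (any(assigned)) {
    s <- tapply(objects$integrated_intensity[assigned],
                objects$parent_cell_id[assigned], sum)
    tot[as.integer(names(s))] <- as.numeric(s)
  }
  data.frame(cell_id = seq_len(n_cells), norm_intensity = tot / area)
}

#' Combine the per-cell granularity statistics
#'
#' Convenience wrapper computing all three per-cell metrics from a segmented
#' field: fraction of cellular area occupied, skewness of the RNA signal, and
#' area-normalized intensity.
#'
#' @param objects assigned object table.
#' @param cell_labels integer cell label matrix.
#' @param image corrected, projected RNA channel.
#' @param condition condition label stored per cell.
#' @param field_id field identifier.
#' @return data.frame: cell_id, field_id, condition, cell_area_px,
#'   frac_area_occupied, skewness, norm_intensity.
#' @export
cell_metrics <- function(objects, cell_labels, image, condition = "control",
                         field_id = 1L) {
  fa <- fraction_area_occupied(objects, cell_labels)
  sk <- cell_skewness(image, cell_labels)
  ni <- normalized_cell_intensity(objects, cell_labels)
  data.frame(cell_id = fa$cell_id, field_id = field_id, condition = condition,
             cell_area_px = fa$cell_area_px,
             frac_area_occupied = fa$frac_area_occupied,
             skewness = sk$skewness, norm_intensity = ni$norm_intensity)
}

#' One-sided two-sample comparison of a per-cell metric between conditions
#'
#' Two-sample t-test of treated vs control in the stated direction, with no
#' multiple-testing adjustment, run on the raw metric values (display may use
#' a log10 axis, the test does not). Welch's unequal-variance form is the
#' default; `var_equal = TRUE` gives the pooled-variance test.
#'
#' @param treated numeric vector of per-cell values in the treated condition.
#' @param control numeric vector in the control condition.
#' @param direction "less" (treated < control) or "greater".
#' @param metric name recorded in the result.
#' @param var_equal use the pooled-variance t-test (default FALSE = Welch).
#' @return data.frame of class `comparison_result`: metric, direction,
#'   n_treated, n_control, statistic, df, p_value, adjustment.
#' @export
compare_conditions <- function(treated, control,
                               direction = c("less", "greater"),
                               metric = "metric", var_equal = FALSE) {
  direction <- match.arg(direction)
  treated <- treated[is.finite(treated)]
  control <- control[is.finite(control)]
  if (length(treated) < 2 || length(control) < 2)
    stop("need at least 2 finite values per group")
  tt <- stats::t.test(treated, control, alternative = direction,
                      var.equal = var_equal)
  out <- data.frame(metric = metric, direction = direction,
                    n_treated = length(treated), n_control = length(control),
                    statistic = unname(tt$statistic), df = unname(tt$parameter),
                    p_value = tt$p.value, adjustment = "none")
  class(out) <- c("comparison_result", class(out))
  out
}
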