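#' Segmentation configuration
#'
#' Settings for RNA-object detection. The defaults reproduce the published
#' CellProfiler-style configuration: minimum cross-entropy (Li) global
#' threshold, threshold smoothing scale 1.3488 (which corresponds to a
#' Gaussian sigma of 1 px under the `scale / 1.3488` convention), correction
#' factor 1, bounds (0, 1), automatic declumping parameters, holes filled
#' after declumping, and no size gate.
#'
#' "Automatic" declumping resolves to: smoothing sigma 1 px and minimum
#' seed distance `max(2, 0.5 * median equivalent diameter of the mask
#' components)` px; both can be overridden numerically.
#'
#' @param smoothing_scale threshold smoothing scale; Gaussian sigma used is
#'   `smoothing_scale / 1.3488` px.
#' @param correction_factor multiplier on the Li threshold before clamping.
#' @param bounds length-2 numeric in [0, 1]: threshold clamp bounds.
#' @param declump_min_distance_px minimum distance between intensity maxima
#'   used as declumping seeds, or "auto".
#' @param declump_smooth_sigma_px Gaussian sigma for the declumping intensity
#'   smoothing, or "auto".
#' @param size_range_px optional (min, max) equivalent diameter gate.
#' @param fill_holes fill enclosed background inside each object (default TRUE).
#' @param declump_on which image drives declumping: the edge-enhanced image
#'   ("enhanced", default) or the original channel ("original").
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(smoothing_scale = 1.3488,
                                correction_factor = 1,
                                bounds = c(0, 1),
                                declump_min_distance_px = "auto",
                                declump_smooth_sigma_px = "auto",
                                size_range_px = NULL,
                                fill_holes = TRUE,
                                declump_on = c("enhanced", "original")) {
  stopifnot(smoothing_scale > 0, correction_factor > 0,
            length(bounds) == 2, bounds[1] >= 0, bounds[2] <= 1,
            bounds[1] <= bounds[2])
  if (!identical(declump_min_distance_px, "auto"))
    stopifnot(is.numeric(declump_min_distance_px), declump_min_distance_px > 0)
  if (!identical(declump_smooth_sigma_px, "auto"))
    stopifnot(is.numeric(declump_smooth_sigma_px), declump_smooth_sigma_px > 0)
  if (!is.null(size_range_px))
    stopifnot(length(size_range_px) == 2, size_range_px[1] <= size_range_px[2])
  structure(list(smoothing_scale = smoothing_scale,
                 correction_factor = correction_factor,
                 bounds = bounds,
                 declump_min_distance_px = declump_min_distance_px,
                 declump_smooth_sigma_px = declump_smooth_sigma_px,
                 size_range_px = size_range_px,
                 fill_holes = fill_holes,
                 declump_on = match.arg(declump_on)),
            class = "segmentation_config")
}

#' Segmentation configuration tuned to diffraction-limited puncta
#'
#' Same defaults as [segmentation_config()] except that the declumping seed
#' distance and smoothing are set from the known spot scale (distance 3 px,
#' sigma 1 px) instead of "auto". The automatic rule derives the seed
#' distance from the median equivalent diameter of the thresholded
#' components, which overestimates it exactly when several diffraction-
#' limited spots chain into one component; when the spot size is known a
#' priori (as for single-molecule FISH puncta), setting the distance from it
#' is the standard practice.
#'
#' @param declump_min_distance_px seed distance in px (default 3).
#' @param ... further arguments passed to [segmentation_config()].
#' @return list of class `segmentation_config`.
#' @export
puncta_segmentation_config <- function(declump_min_distance_px = 3, ...) {
  segmentation_config(declump_min_distance_px = declump_min_distance_px,
                      declump_smooth_sigma_px = 1, ...)
}

# the 8 Kirsch compass kernels: the base kernel's outer ring
# [5,5,5,-3,-3,-3,-3,-3] rotated through the 8 ring positions
#' @noRd
kirsch_kernels <- function() {
  ring <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  base <- c(5, 5, 5, -3, -3, -3, -3, -3)
  lapply(0:7, function(k) {
    w <- base[((seq_len(8) - 1 - k) %% 8) + 1]
    K <- matrix(0, 3, 3)
    K[cbind(ring[, 1] + 2, ring[, 2] + 2)] <- w
    K
  })
}

#' Kirsch compass edge enhancement
#'
#' Applies the 8-direction Kirsch compass operator: the image is correlated
#' with each of the 8 rotations of the kernel
#' `[[5,5,5],[-3,0,-3],[-3,-3,-3]]` (reflect padding at the borders) and the
#' per-pixel maximum response is kept; negative responses are clamped to 0.
#'
#' @param image 2-D numeric matrix.
#' @return 2-D matrix of non-negative edge responses, same shape.
#' @export
kirsch_enhance <- function(image) {
  if (length(dim(image)) != 2) stop("kirsch_enhance expects a 2-D image")
  H <- nrow(image); W <- ncol(image)
  # reflect padding by one pixel
  P <- matrix(0, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- image
  P[1, 2:(W + 1)] <- image[1, ]; P[H + 2, 2:(W + 1)] <- image[H, ]
  P[2:(H + 1), 1] <- image[, 1]; P[2:(H + 1), W + 2] <- image[, W]
  P[1, 1] <- image[1, 1]; P[1, W + 2] <- image[1, W]
  P[H + 2, 1] <- image[H, 1]; P[H + 2, W + 2] <- image[H, W]

  shifts <- lapply(-1:1, function(dy) lapply(-1:1, function(dx)
    P[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]))
  best <- matrix(-Inf, H, W)
  for (K in kirsch_kernels()) {
    resp <- matrix(0, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      w <- K[dy + 2, dx + 2]
      if (w != 0) resp <- resp + w * shifts[[dy + 2]][[dx + 2]]
    }
    best <- pmax(best, resp)
  }
  pmax(best, 0)
}

#' Minimum cross-entropy (Li) global threshold
#'
#' Rescales the image to [0, 1] over its full intensity range, smooths it
#' with a Gaussian of sigma `smoothing_scale / 1.3488` px, and computes Li's
#' iterative minimum cross-entropy threshold on the smoothed image. The
#' iteration starts at the image mean and updates
#' `t <- (mu_b - mu_f) / (log(mu_b) - log(mu_f))` with `mu_b`, `mu_f` the
#' means below/above `t`, converging at `|dt| < 0.5/65535` (max 200
#' iterations). The estimate is multiplied by `correction_factor` and clamped
#' to `bounds`; the mask is `smoothed > threshold`.
#'
#' @param image 2-D numeric matrix.
#' @param cfg a [segmentation_config()].
#' @return list: `threshold` (final, clamped), `threshold_raw` (pre-scaling
#'   Li estimate), `mask` (logical matrix), `smoothed` (the smoothed rescaled
#'   image the threshold applies to).
#' @export
li_threshold <- function(image, cfg = segmentation_config()) {
  if (length(dim(image)) != 2) stop("li_threshold expects a 2-D image")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: threshold undefined, returning empty mask")
    return(list(threshold = NA_real_, threshold_raw = NA_real_,
                mask = matrix(FALSE, nrow(image), ncol(image)),
                smoothed = image * 0))
  }
  x <- rescale01(image)
  sm <- gauss_blur(x, cfg$smoothing_scale / 1.3488)
  t_raw <- li_iterative(sm)
  thr <- clamp(t_raw * cfg$correction_factor, cfg$bounds[1], cfg$bounds[2])
  list(threshold = thr, threshold_raw = t_raw, mask = sm > thr, smoothed = sm)
}

# Li & Tam fixed-point iteration for the minimum cross-entropy threshold
#' @noRd
li_iterative <- function(x, tol = 0.5 / 65535, max_iter = 200L) {
  v <- as.numeric(x)
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    mb <- mean(v[v <= t_cur]); mf <- mean(v[v > t_cur])
    if (!is.finite(mb)) mb <- 0
    if (!is.finite(mf)) mf <- t_cur
    mb <- max(mb, 1e-12); mf <- max(mf, 1e-12)
    if (mb == mf) break
    t_new <- (mb - mf) / (log(mb) - log(mf))
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur
}

#' Cross-entropy of a binarisation at a given threshold
#'
#' The objective Li's iteration minimises:
#' `-(S_b * log(mu_b) + S_f * log(mu_f))` where `S_b`, `S_f` are the sums and
#' `mu_b`, `mu_f` the means of the pixels below/above the threshold. Exposed
#' so exhaustive minimisation can serve as an independent check of the
#' iterative estimate.
#'
#' @param x numeric vector or matrix of (smoothed) pixel values.
#' @param threshold candidate threshold.
#' @return the cross-entropy value (smaller is better).
#' @export
cross_entropy <- function(x, threshold) {
  v <- as.numeric(x)
  b <- v[v <= threshold]; f <- v[v > threshold]
  term <- function(s) {
    if (length(s) == 0 || sum(s) <= 0) return(0)
    sum(s) * log(mean(s))
  }
  -(term(b) + term(f))
}

# local maxima of `img` inside `mask` with a minimum separation;
# greedy suppression in decreasing intensity order
#' @noRd
local_maxima <- function(img, mask, min_distance) {
  H <- nrow(img); W <- ncol(img)
  P <- matrix(-Inf, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- img
  nb_max <- matrix(-Inf, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, P[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)])
  }
  cand <- which(mask & img >= nb_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cand)
  ord <- order(img[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        min(sqrt((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2)) >= min_distance) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Split clumped objects by intensity (declumping)
#'
#' Seeds are the local maxima of the Gaussian-smoothed intensity inside the
#' mask, thinned to a minimum mutual distance; labels are then grown from the
#' seeds across the mask with intensity-weighted propagation, so dividing
#' lines fall along intensity valleys. Holes enclosed by each object are
#' filled afterwards, and objects outside the configured equivalent-diameter
#' range (if any) are removed. "auto" parameters resolve as documented in
#' [segmentation_config()].
#'
#' @param mask logical 2-D matrix (foreground).
#' @param intensity 2-D matrix guiding seed detection and dividing lines.
#' @param cfg a [segmentation_config()].
#' @return integer label matrix with contiguous labels 1..N (0 = background).
#' @export
declump <- function(mask, intensity, cfg = segmentation_config()) {
  stopifnot(identical(dim(mask), dim(intensity)))
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))

  sigma <- cfg$declump_smooth_sigma_px
  if (identical(sigma, "auto")) sigma <- 1
  sm <- gauss_blur(intensity, sigma)

  comp <- as.matrix(EBImage::bwlabel(mask))
  min_dist <- cfg$declump_min_distance_px
  if (identical(min_dist, "auto")) {
    areas <- tabulate(comp[comp > 0])
    eq_diam <- 2 * sqrt(areas / pi)
    min_dist <- max(2, 0.5 * stats::median(eq_diam))
  }

  seeds_rc <- local_maxima(sm, mask, min_dist)
  if (nrow(seeds_rc) == 0) {
    labels <- comp
  } else {
    seeds <- matrix(0L, nrow(mask), ncol(mask))
    seeds[seeds_rc] <- seq_len(nrow(seeds_rc))
    labels <- as.matrix(EBImage::propagate(sm, seeds, mask = mask,
                                           lambda = 1e-4))
    storage.mode(labels) <- "integer"
    # mask pixels unreachable from any seed (disconnected components with no
    # maximum survive as their own objects)
    orphan <- mask & labels == 0L
    if (any(orphan)) {
      extra <- as.matrix(EBImage::bwlabel(orphan))
      labels[orphan] <- max(labels) + extra[orphan]
    }
  }
  if (cfg$fill_holes) {
    # fill per-object holes, then holes enclosed jointly by several objects
    # (a clump split into arcs): grow the surrounding labels into them
    labels <- as.matrix(EBImage::fillHull(labels))
    storage.mode(labels) <- "integer"
    filled_mask <- as.matrix(EBImage::fillHull(labels > 0)) > 0
    if (any(filled_mask & labels == 0L)) {
      labels <- as.matrix(EBImage::propagate(matrix(0, nrow(mask), ncol(mask)),
                                             labels, mask = filled_mask))
      storage.mode(labels) <- "integer"
    }
  }
  if (!is.null(cfg$size_range_px)) {
    areas <- tabulate(labels[labels > 0])
    eq_diam <- 2 * sqrt(areas / pi)
    bad <- which(eq_diam < cfg$size_range_px[1] | eq_diam > cfg$size_range_px[2])
    labels[labels %in% bad] <- 0L
  }
  relabel(labels)
}

#' Measure labeled objects on the original channel
#'
#' Per-object area (pixel count), integrated intensity (sum of original
#' channel pixels over the object support) and intensity-weighted centroid
#' (0-based row/col; falls back to the unweighted centroid for zero-intensity
#' objects).
#'
#' @param labels integer label matrix.
#' @param original 2-D matrix, the unenhanced channel intensities.
#' @param field_id identifier stored in the table (default 1).
#' @return data.frame: field_id, object_id, parent_cell_id (0 = unassigned),
#'   area_px, integrated_intensity, centroid_row, centroid_col.
#' @export
measure_objects <- function(labels, original, field_id = 1L) {
  stopifnot(identical(dim(labels), dim(original)))
  ids <- sort(unique(as.integer(labels[labels > 0])))
  empty <- data.frame(field_id = integer(0), object_id = integer(0),
                      parent_cell_id = integer(0), area_px = integer(0),
                      integrated_intensity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  if (length(ids) == 0) return(empty)
  idx <- which(labels > 0)
  lab <- as.integer(labels[idx])
  inten <- as.numeric(original[idx])
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  area <- as.integer(tapply(lab, lab, length))
  tot <- as.numeric(tapply(inten, lab, sum))
  wr <- as.numeric(tapply(inten * rows, lab, sum))
  wc <- as.numeric(tapply(inten * cols, lab, sum))
  ur <- as.numeric(tapply(rows, lab, mean))
  uc <- as.numeric(tapply(cols, lab, mean))
  cr <- ifelse(tot > 0, wr / tot, ur) - 1
  cc <- ifelse(tot > 0, wc / tot, uc) - 1
  data.frame(field_id = field_id, object_id = ids, parent_cell_id = 0L,
             area_px = area, integrated_intensity = tot,
             centroid_row = cr, centroid_col = cc)
}

#' Segment RNA objects in a corrected, projected RNA channel
#'
#' The full detection chain: rescale to the full intensity range, enhance
#' borders with the Kirsch compass operator, threshold with the minimum
#' cross-entropy method, declump with intensity-guided watershed-style
#' division, fill holes, and measure each object on the original
#' (pre-enhancement) channel. If a cell label map is supplied, objects are
#' assigned to cells by maximal overlap.
#'
#' @param rna_image 2-D matrix, corrected and z-projected RNA channel.
#' @param cfg a [segmentation_config()].
#' @param cells optional integer cell label map for parent assignment.
#' @param field_id identifier propagated to the object table.
#' @return list: `labels` (object label matrix), `objects` (object table),
#'   `threshold` (the Li threshold used), `enhanced` (edge-enhanced image).
#' @export
segment_rna <- function(rna_image, cfg = segmentation_config(), cells = NULL,
                        field_id = 1L) {
  x <- rescale01(rna_image)
  enh <- kirsch_enhance(x)
  th <- li_threshold(enh, cfg)
  driver <- if (cfg$declump_on == "enhanced") th$smoothed else x
  labels <- declump(th$mask, driver, cfg)
  objects <- measure_objects(labels, rna_image, field_id = field_id)
  if (!is.null(cells)) {
    objects <- assign_objects_to_cells(objects, labels, cells)
  }
  list(labels = labels, objects = objects, threshold = th$threshold,
       enhanced = enh)
}

#' Assign segmented objects to parent cells by maximal overlap
#'
#' Each object is assigned to the cell with which it shares the most pixels;
#' ties are broken by the larger overlap fraction of the cell's area, then by
#' the smaller cell label. Objects overlapping no cell get parent 0 and are
#' excluded from per-cell metrics downstream.
#'
#' @param objects object table from [measure_objects()].
#' @param object_labels integer object label matrix the table was measured on.
#' @param cell_labels integer cell label matrix.
#' @return the object table with `parent_cell_id` filled in.
#' @export
assign_objects_to_cells <- function(objects, object_labels, cell_labels) {
  stopifnot(identical(dim(object_labels), dim(cell_labels)))
  if (nrow(objects) == 0) return(objects)
  cell_area <- tabulate(cell_labels[cell_labels > 0])
  idx <- object_labels > 0 & cell_labels > 0
  objects$parent_cell_id <- 0L
  if (!any(idx)) return(objects)
  ov <- stats::aggregate(
    list(overlap = rep(1L, sum(idx))),
    by = list(object = as.integer(object_labels[idx]),
              cell = as.integer(cell_labels[idx])),
    FUN = sum)
  ov$cell_frac <- ov$overlap / cell_area[ov$cell]
  for (i in seq_len(nrow(objects))) {
    sub <- ov[ov$object == objects$object_id[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(-sub$overlap, -sub$cell_frac, sub$cell), , drop = FALSE]
    objects$parent_cell_id[i] <- sub$cell[1]
  }
  objects
}
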