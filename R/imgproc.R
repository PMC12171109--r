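#' A multi-channel fluorescence field
#'
#' Lightweight container for a corrected or raw multi-channel image. Each
#' channel is a 2-D matrix or a 3-D array (rows x cols x z). Channel roles are
#' carried in the list names (conventionally `rna`, `cellstain`, `nuclei`).
#' After flat-field correction pixel values are dimensionless ratios and may
#' exceed 1.
#'
#' @param channels named list of numeric matrices/arrays, all the same shape.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um optional z step in micrometres (for stacks).
#' @param corrected logical provenance flag: flat-field corrected.
#' @param projected logical provenance flag: z-projected.
#' @return object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size_um = 0.108, z_step_um = NULL,
                        corrected = FALSE, projected = FALSE) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))),
            pixel_size_um > 0)
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1)
    stop("all channels must share the same shape")
  if (any(vapply(channels, function(ch) any(ch < 0, na.rm = TRUE), logical(1))) &&
      !corrected)
    stop("raw channel pixels must be non-negative")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, corrected = corrected,
                 projected = projected),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("field_image:", paste(names(x$channels), collapse = ", "),
      "| shape", paste(d, collapse = "x"),
      "| pixel", x$pixel_size_um, "um",
      if (x$corrected) "| corrected" else "",
      if (x$projected) "| projected" else "", "\n")
  invisible(x)
}

#' Average a set of empty-well flat-field images
#'
#' Pixelwise arithmetic mean of the empty-well fields acquired with the
#' sample's microscope settings.
#'
#' @param fields list of 2-D numeric matrices of identical shape.
#' @return 2-D matrix, the mean field.
#' @export
average_flatfield <- function(fields) {
  stopifnot(is.list(fields), length(fields) >= 1)
  d0 <- dim(fields[[1]])
  for (i in seq_along(fields)) {
    if (!identical(dim(fields[[i]]), d0))
      stop("flat-field ", i, " has shape ", paste(dim(fields[[i]]), collapse = "x"),
           ", expected ", paste(d0, collapse = "x"))
  }
  Reduce(`+`, fields) / length(fields)
}

#' Flat-field (illumination) correction
#'
#' Subtracts the camera dark level from both the sample and the averaged
#' empty-well image, then divides the sample by the background, per channel
#' and per z-slice. Pixels where the dark-subtracted flat falls below
#' `eps = 1e-6 * max(flat)` are clamped there; the number of clamped pixels is
#' recorded in the `clamped_px` attribute of the result.
#'
#' @param sample a [field_image()] or a single numeric matrix/array.
#' @param flat 2-D averaged flat-field (see [average_flatfield()]).
#' @param dark scalar dark offset or a 2-D dark frame (default 0).
#' @return same type as `sample`, corrected; for a `field_image` the
#'   `corrected` flag is set.
#' @export
flatfield_correct <- function(sample, flat, dark = 0) {
  stopifnot(is.matrix(flat))
  denom <- flat - dark
  if (all(denom <= 0))
    stop("flat-field is not above the dark level anywhere; correction undefined")
  eps <- 1e-6 * max(flat)
  clamped <- sum(denom < eps)
  denom <- pmax(denom, eps)

  correct_one <- function(x) {
    if (length(dim(x)) == 3) {
      out <- x
      for (z in seq_len(dim(x)[3])) out[, , z] <- (x[, , z] - dark) / denom
      out
    } else {
      (x - dark) / denom
    }
  }
  if (inherits(sample, "field_image")) {
    out <- sample
    out$channels <- lapply(sample$channels, correct_one)
    out$corrected <- TRUE
    attr(out, "clamped_px") <- clamped
    out
  } else {
    out <- correct_one(sample)
    attr(out, "clamped_px") <- clamped
    out
  }
}

#' Sum z-projection
#'
#' Collapses a z-stack to 2-D by summing the slices of each channel; total
#' intensity is conserved exactly.
#'
#' @param img a [field_image()] (3-D channels) or a 3-D array.
#' @return same type, 2-D, with the `projected` flag set on a `field_image`.
#' @export
sum_project <- function(img) {
  project_one <- function(x) {
    if (length(dim(x)) == 3) {
      rowSums(x, dims = 2)
    } else {
      warning("input is already 2-D; returning unchanged")
      x
    }
  }
  if (inherits(img, "field_image")) {
    img$channels <- lapply(img$channels, project_one)
    img$projected <- TRUE
    img
  } else {
    project_one(img)
  }
}
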