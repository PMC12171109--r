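#' Read a multi-page TIFF stack as a matrix or 3-D array
#'
#' Multi-page TIFFs are read as z-stacks (rows x cols x z); single pages as
#' 2-D matrices. Values are returned on the package's camera-count scale:
#' stored samples (normalized to [0, 1] in the file) are multiplied by
#' 65535, so a 16-bit file round-trips its integer counts exactly and a
#' 32-bit file carries fractional values (corrected ratios) at ~1e-5
#' absolute resolution.
#'
#' @param path TIFF file path.
#' @return numeric matrix or 3-D array.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) p * 65535)
  if (length(pages) == 1) return(pages[[1]])
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  arr
}

#' Write a matrix or z-stack to TIFF
#'
#' Values are stored on the camera-count scale (divided by 65535 in the
#' file, the inverse of [read_tiff_stack()]). Use 16 bits for integer count
#' images and label maps, 32 bits for corrected/projected images whose
#' values are fractional.
#'
#' @param x numeric matrix or 3-D array (rows x cols x z), in 0..65535.
#' @param path output file.
#' @param bits bits per sample: 16 or 32.
#' @export
write_tiff_stack <- function(x, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  if (any(x < 0 | x > 65535))
    stop("TIFF output requires values in 0..65535 (counts scale)")
  pages <- if (length(dim(x)) == 3) {
    lapply(seq_len(dim(x)[3]), function(z) x[, , z])
  } else list(x)
  pages <- lapply(pages, function(p) {
    (if (bits == 16L) round(p) else p) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a multi-channel field from per-channel TIFF files
#'
#' @param paths named character vector of TIFF paths; names are the channel
#'   roles (`rna`, `cellstain`, `nuclei`).
#' @param pixel_size_um lateral pixel size.
#' @param z_step_um optional z step.
#' @return a [field_image()].
#' @export
read_image_stack <- function(paths, pixel_size_um = 0.108, z_step_um = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("channel layout unknown: `paths` must be named by channel role")
  channels <- lapply(paths, read_tiff_stack)
  field_image(channels, pixel_size_um = pixel_size_um, z_step_um = z_step_um)
}

#' Read and write integer label maps as 16-bit TIFF
#'
#' @param path TIFF file path.
#' @return integer label matrix.
#' @export
read_label_map <- function(path) {
  m <- round(read_tiff_stack(path))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_map
#' @param labels integer label matrix to write.
#' @export
write_label_map <- function(labels, path) {
  write_tiff_stack(labels, path, bits = 16L)
}

#' Read a tidy count table CSV with validation
#'
#' Requires columns transcript, sample_id, condition, timepoint_h,
#' replicate, fraction, count. Leading `#` comment lines (provenance
#' headers) are skipped. Negative counts and duplicate
#' (transcript, sample_id, fraction) rows are rejected with the offending
#' rows named.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_counts <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("transcript", "sample_id", "condition", "timepoint_h",
                "replicate", "fraction", "count")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0)
    stop("count table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$count < 0))
    stop("negative count in row(s): ",
         paste(utils::head(which(tab$count < 0), 5), collapse = ", "))
  key <- paste(tab$transcript, tab$sample_id, tab$fraction)
  if (anyDuplicated(key))
    stop("duplicate (transcript, sample, fraction) row(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  tab[order(tab$timepoint_h), , drop = FALSE]
}

#' Write a table as CSV with a provenance comment header
#'
#' Prepends a `#` comment line carrying the package version and an optional
#' provenance tag (e.g. a config hash or seed) so every output file records
#' where it came from; [read_counts()] and plain `read.csv(comment.char =
#' "#")` skip it.
#'
#' @param tab data.frame to write.
#' @param path output CSV path.
#' @param provenance optional character tag for the header line.
#' @export
write_table_csv <- function(tab, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("mitogranule"))
  tag <- if (is.null(provenance)) "" else paste0(" | ", provenance)
  writeLines(paste0("# mitogranule v", ver, tag), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
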