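#' Rescale an image to the unit interval over its full range
#'
#' Linear rescale of a numeric matrix so that its minimum maps to 0 and its
#' maximum to 1. A constant image is returned as all zeros (the caller decides
#' whether that is an error).
#'
#' @param x numeric matrix or array.
#' @return numeric object of the same shape with values in [0, 1].
#' @export
rescale01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng))) stop("image contains no finite values")
  if (rng[2] == rng[1]) {
    return(x * 0)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @keywords internal
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# integer pixel offsets of a filled disk of the given radius (in px)
#' @noRd
disk_offsets <- function(radius) {
  r <- max(0, radius)
  k <- ceiling(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# add `value` on a filled disk centred at (row, col); in-place on a copy
#' @noRd
paint_disk <- function(mat, row, col, radius, value) {
  off <- disk_offsets(radius)
  rr <- round(row) + off$dr
  cc <- round(col) + off$dc
  ok <- rr >= 1 & rr <= nrow(mat) & cc >= 1 & cc <= ncol(mat)
  idx <- cbind(rr[ok], cc[ok])
  mat[idx] <- mat[idx] + value
  mat
}

# Gaussian blur that tolerates sigma = 0 (identity)
#' @noRd
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.matrix(EBImage::gblur(x, sigma = sigma))
}

# relabel a label matrix so labels are contiguous 1..N (order preserved)
#' @noRd
relabel <- function(labels) {
  u <- sort(unique(as.integer(labels)))
  u <- u[u > 0]
  if (length(u) == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- lut[as.integer(labels[pos])]
  out
}
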