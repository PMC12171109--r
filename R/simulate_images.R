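#' Parameters for the synthetic fluorescence field generator
#'
#' Bundles and validates every knob of the image forward model. The model
#' emulates adherent cells whose filamentous mitochondrial network carries
#' RNA-FISH puncta in either a diffuse state (puncta spread along the network)
#' or a granular state (puncta concentrated around a few granule centres), as
#' seen by a widefield/spinning-disk camera: Gaussian PSF, smooth illumination
#' bias, dark offset, Poisson shot noise and Gaussian read noise.
#'
#' All granule-related parameters are ignored when `granular = FALSE`.
#' Identical parameters and seed give bit-identical output.
#'
#' @param field_size_px integer pair, image height and width in pixels.
#' @param n_cells number of cells to place (0 allowed).
#' @param cell_radius_px range (min, max) of the mean cell radius in px.
#' @param network_branches number of mitochondrial branches per cell.
#' @param network_width_px dilation width of the network skeleton in px.
#' @param n_puncta_per_cell RNA puncta planted per cell (0 allowed).
#' @param granular logical; if TRUE puncta cluster around granule centres.
#' @param min_punctum_sep_px minimum separation (px) enforced between puncta
#'   in the diffuse state, emulating resolvable single-molecule FISH spots;
#'   relaxed automatically if the network cannot accommodate it. Ignored in
#'   the granular state, whose point is unresolvable clustering.
#' @param n_granules_per_cell Poisson mean of granule centres per cell.
#' @param granule_sigma_px Gaussian scatter (sd, px) of puncta around centres.
#' @param punctum_radius_px radius of a single punctum footprint in px.
#' @param intensity_scale photon-count amplitude of one punctum.
#' @param decay_factor multiplier in (0, 1] applied to total RNA signal
#'   (models lower abundance in a treated condition).
#' @param psf_sigma_px Gaussian PSF sigma in px (0 = no blur).
#' @param illum_gradient_amp amplitude of the radial illumination falloff
#'   (0 = flat illumination; 0.2 means corners at 80\% of centre).
#' @param dark_offset camera dark offset in counts.
#' @param read_noise_sd Gaussian read-noise sd in counts.
#' @param shot_noise logical; apply Poisson shot noise (default TRUE). Set
#'   FALSE together with `read_noise_sd = 0` for a fully noiseless field.
#' @param network_baseline intensity of the network itself in the RNA channel
#'   (default 0: the RNA channel carries puncta only).
#' @param condition character label stored in the exported truth; default
#'   "granular" or "diffuse" according to `granular`.
#' @param seed integer seed for the generator's single RNG stream.
#' @return a validated list of class `image_sim_params`.
#' @export
image_sim_params <- function(field_size_px = c(512L, 512L),
                             n_cells = 8L,
                             cell_radius_px = c(45, 60),
                             network_branches = 6L,
                             network_width_px = 3,
                             n_puncta_per_cell = 30L,
                             granular = FALSE,
                             min_punctum_sep_px = 5,
                             n_granules_per_cell = 5,
                             granule_sigma_px = 3,
                             punctum_radius_px = 1.5,
                             intensity_scale = 2000,
                             decay_factor = 1,
                             psf_sigma_px = 1.3,
                             illum_gradient_amp = 0.2,
                             dark_offset = 100,
                             read_noise_sd = 3,
                             shot_noise = TRUE,
                             network_baseline = 0,
                             condition = NULL,
                             seed = 1L) {
  stopifnot(length(field_size_px) == 2, all(field_size_px >= 16),
            n_cells >= 0, length(cell_radius_px) == 2,
            all(cell_radius_px > 0), cell_radius_px[1] <= cell_radius_px[2],
            network_branches >= 1, network_width_px > 0,
            n_puncta_per_cell >= 0, is.logical(granular),
            min_punctum_sep_px >= 0,
            n_granules_per_cell > 0, granule_sigma_px > 0,
            punctum_radius_px > 0, intensity_scale > 0,
            decay_factor > 0, decay_factor <= 1,
            psf_sigma_px >= 0, illum_gradient_amp >= 0,
            dark_offset >= 0, read_noise_sd >= 0, is.logical(shot_noise),
            network_baseline >= 0)
  if (is.null(condition)) condition <- if (granular) "granular" else "diffuse"
  structure(list(
    field_size_px = as.integer(field_size_px), n_cells = as.integer(n_cells),
    cell_radius_px = cell_radius_px, network_branches = as.integer(network_branches),
    network_width_px = network_width_px, n_puncta_per_cell = as.integer(n_puncta_per_cell),
    granular = granular, min_punctum_sep_px = min_punctum_sep_px,
    n_granules_per_cell = n_granules_per_cell,
    granule_sigma_px = granule_sigma_px, punctum_radius_px = punctum_radius_px,
    intensity_scale = intensity_scale, decay_factor = decay_factor,
    psf_sigma_px = psf_sigma_px, illum_gradient_amp = illum_gradient_amp,
    dark_offset = dark_offset, read_noise_sd = read_noise_sd,
    shot_noise = shot_noise,
    network_baseline = network_baseline, condition = condition,
    seed = as.integer(seed)), class = "image_sim_params")
}

# smooth radial illumination field: 1 at the centre, 1 - amp at the corners;
# a deterministic function of the field size and amplitude only, so sample
# fields and empty-well flat-fields share it exactly
#' @noRd
illumination_field <- function(dim, amp) {
  H <- dim[1]; W <- dim[2]
  ry <- (seq_len(H) - 0.5) / H - 0.5
  rx <- (seq_len(W) - 0.5) / W - 0.5
  r2 <- outer(ry^2, rx^2, "+")
  1 - amp * r2 / 0.5
}

# rasterize one radial-harmonic perturbed disk into the label matrix
#' @noRd
rasterize_cell <- function(labels, center, radius, harm_k, harm_a, harm_phi,
                           label) {
  H <- nrow(labels); W <- ncol(labels)
  rmax <- radius * 1.3
  r1 <- max(1L, floor(center[1] - rmax)); r2 <- min(H, ceiling(center[1] + rmax))
  c1 <- max(1L, floor(center[2] - rmax)); c2 <- min(W, ceiling(center[2] + rmax))
  dr <- matrix(seq(r1, r2) - center[1], nrow = r2 - r1 + 1, ncol = c2 - c1 + 1)
  dc <- matrix(seq(c1, c2) - center[2], nrow = r2 - r1 + 1, ncol = c2 - c1 + 1,
               byrow = TRUE)
  theta <- atan2(dr, dc)
  rb <- radius * (1 + Reduce(`+`, Map(function(k, a, p) a * cos(k * theta + p),
                                      harm_k, harm_a, harm_phi)))
  inside <- sqrt(dr^2 + dc^2) <= rb
  sub <- labels[r1:r2, c1:c2]
  sub[inside & sub == 0L] <- label
  labels[r1:r2, c1:c2] <- sub
  labels
}

# persistent random walks from the nucleus boundary; returns skeleton pixels
#' @noRd
grow_network <- function(cell_mask, center, nucleus_radius, n_branches) {
  H <- nrow(cell_mask); W <- ncol(cell_mask)
  pix <- matrix(numeric(0), ncol = 2)
  n_steps <- round(2.5 * sqrt(sum(cell_mask) / pi))
  for (b in seq_len(n_branches)) {
    ang <- stats::runif(1, 0, 2 * pi)
    pos <- center + nucleus_radius * c(sin(ang), cos(ang))
    dir <- ang
    branch <- matrix(NA_real_, n_steps, 2)
    for (s in seq_len(n_steps)) {
      dir <- dir + stats::rnorm(1, 0, 0.35)
      cand <- pos + c(sin(dir), cos(dir))
      ri <- round(cand[1]); ci <- round(cand[2])
      if (ri < 1 || ri > H || ci < 1 || ci > W || !cell_mask[ri, ci]) {
        # bounce: turn away and retry next step
        dir <- dir + pi / 2 + stats::rnorm(1, 0, 0.5)
        next
      }
      pos <- cand
      branch[s, ] <- c(ri, ci)
    }
    pix <- rbind(pix, branch[stats::complete.cases(branch), , drop = FALSE])
  }
  unique(pix)
}

#' Simulate one multi-channel fluorescence field with ground truth
#'
#' Generates a three-channel field (RNA-FISH, cell stain, nuclei) containing
#' `n_cells` non-overlapping cells. Each cell carries a branched mitochondrial
#' network; RNA puncta are placed on the network either uniformly
#' (`granular = FALSE`) or scattered around Poisson-many granule centres
#' (`granular = TRUE`). The clean signal is scaled by `decay_factor`, blurred
#' by a Gaussian PSF, multiplied by a smooth illumination field, offset by the
#' camera dark level, and corrupted by Poisson shot noise plus Gaussian read
#' noise, in that order.
#'
#' The exported truth contains the cell label map, punctum coordinates
#' (0-based row/col), per-cell area and the true occupied-area fraction of the
#' noiseless punctum support clipped to the cell.
#'
#' @param params an [image_sim_params()] object.
#' @return list with elements `image` (a [field_image()]), `truth` (list:
#'   `cell_labels` integer matrix, `cells` data.frame, `puncta` data.frame,
#'   `condition`), and `clean` (noiseless pre-optics channel matrices).
#' @export
simulate_field <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(params$seed)
  H <- params$field_size_px[1]; W <- params$field_size_px[2]

  cell_labels <- matrix(0L, H, W)
  nuclei_clean <- matrix(0, H, W)
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  placed <- 0L
  for (i in seq_len(params$n_cells)) {
    for (try in seq_len(1000)) {
      R <- stats::runif(1, params$cell_radius_px[1], params$cell_radius_px[2])
      ctr <- c(stats::runif(1, R * 1.27, H - R * 1.27),
               stats::runif(1, R * 1.27, W - R * 1.27))
      ok <- placed == 0L ||
        all(sqrt(rowSums((centers - matrix(ctr, placed, 2, byrow = TRUE))^2)) >
              1.26 * (radii + R))
      if (ok) {
        placed <- placed + 1L
        centers <- rbind(centers, ctr)
        radii <- c(radii, R)
        hk <- 3:5
        ha <- stats::runif(3, 0, 0.25 / 3)
        hp <- stats::runif(3, 0, 2 * pi)
        cell_labels <- rasterize_cell(cell_labels, ctr, R, hk, ha, hp, placed)
        nuclei_clean <- paint_disk(nuclei_clean, ctr[1], ctr[2], 0.35 * R,
                                   0.5 * params$intensity_scale)
        break
      }
    }
  }
  n_cells <- placed

  rna_clean <- matrix(0, H, W)
  network_all <- matrix(FALSE, H, W)
  puncta <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0))
  brush_w <- max(1L, 2L * floor(params$network_width_px / 2) + 1L)
  brush <- if (brush_w >= 3) EBImage::makeBrush(brush_w, shape = "disc") else NULL

  for (k in seq_len(n_cells)) {
    cmask <- cell_labels == k
    skel <- grow_network(cmask, centers[k, ], 0.35 * radii[k],
                         params$network_branches)
    net <- matrix(FALSE, H, W)
    if (nrow(skel) > 0) net[skel] <- TRUE
    if (!is.null(brush)) {
      net <- as.matrix(EBImage::dilate(net, brush)) > 0
    }
    net <- net & cmask
    network_all <- network_all | net
    netpix <- which(net, arr.ind = TRUE)
    if (nrow(netpix) == 0 || params$n_puncta_per_cell == 0) next

    n_p <- params$n_puncta_per_cell
    if (!params$granular) {
      # greedy placement with a minimum mutual separation; relax the
      # separation if the network cannot host that many resolved spots
      ord <- netpix[sample.int(nrow(netpix)), , drop = FALSE]
      sep <- params$min_punctum_sep_px
      repeat {
        acc <- matrix(numeric(0), ncol = 2)
        for (j in seq_len(nrow(ord))) {
          p <- ord[j, ]
          if (nrow(acc) == 0 ||
              min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= sep^2) {
            acc <- rbind(acc, p)
            if (nrow(acc) == n_p) break
          }
        }
        if (nrow(acc) == n_p || sep <= 0) break
        sep <- sep - 1
      }
      if (nrow(acc) < n_p) {
        extra <- netpix[sample.int(nrow(netpix), n_p - nrow(acc),
                                   replace = TRUE), , drop = FALSE]
        acc <- rbind(acc, extra)
      }
      pr <- acc[, 1]; pc <- acc[, 2]
    } else {
      G <- max(1L, stats::rpois(1, params$n_granules_per_cell))
      gsel <- netpix[sample.int(nrow(netpix), G, replace = TRUE), , drop = FALSE]
      assign_g <- sample.int(G, n_p, replace = TRUE)
      pr <- pc <- numeric(n_p)
      for (j in seq_len(n_p)) {
        gc <- gsel[assign_g[j], ]
        for (try in seq_len(50)) {
          cand <- round(gc + stats::rnorm(2, 0, params$granule_sigma_px))
          if (cand[1] >= 1 && cand[1] <= H && cand[2] >= 1 && cand[2] <= W &&
              cmask[cand[1], cand[2]]) break
          cand <- gc
        }
        pr[j] <- cand[1]; pc[j] <- cand[2]
      }
    }
    for (j in seq_along(pr)) {
      rna_clean <- paint_disk(rna_clean, pr[j], pc[j], params$punctum_radius_px,
                              params$intensity_scale)
    }
    puncta <- rbind(puncta, data.frame(cell_id = k, row = pr, col = pc))
  }
  if (params$network_baseline > 0) {
    rna_clean <- rna_clean + network_all * params$network_baseline
  }
  rna_clean <- rna_clean * params$decay_factor
  cellstain_clean <- (cell_labels > 0) * 0.25 * params$intensity_scale

  # truth: occupied fraction of the noiseless RNA support, clipped per cell
  support <- rna_clean > 0
  cells_df <- if (n_cells > 0) {
    area <- tabulate(cell_labels[cell_labels > 0], nbins = n_cells)
    occ <- vapply(seq_len(n_cells), function(k)
      sum(support & cell_labels == k) / area[k], numeric(1))
    data.frame(cell_id = seq_len(n_cells), area_px = area,
               true_frac_occupied = occ, condition = params$condition)
  } else {
    data.frame(cell_id = integer(0), area_px = integer(0),
               true_frac_occupied = numeric(0), condition = character(0))
  }

  camera <- function(clean) {
    x <- gauss_blur(clean, params$psf_sigma_px)
    x <- x * illumination_field(c(H, W), params$illum_gradient_amp)
    x <- x + params$dark_offset
    if (params$shot_noise) x <- stats::rpois(length(x), pmax(x, 0))
    if (params$read_noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, params$read_noise_sd)
    matrix(round(clamp(x, 0, 65535)), H, W)
  }
  img <- field_image(
    channels = list(rna = camera(rna_clean),
                    cellstain = camera(cellstain_clean),
                    nuclei = camera(nuclei_clean)),
    pixel_size_um = 0.108)

  truth_puncta <- data.frame(cell_id = puncta$cell_id,
                             row = puncta$row - 1, col = puncta$col - 1)
  list(image = img,
       truth = list(cell_labels = cell_labels, cells = cells_df,
                    puncta = truth_puncta, condition = params$condition),
       clean = list(rna = rna_clean, cellstain = cellstain_clean,
                    nuclei = nuclei_clean))
}

#' Simulate a stack of empty-well flat-field images plus dark frame
#'
#' Emulates the calibration acquisition in which several fields of view of an
#' empty well are imaged with the sample's laser settings. Each field is the
#' product of a constant emission level and the smooth illumination field,
#' plus the camera dark offset, with Poisson and Gaussian read noise. The
#' noiseless dark frame is returned alongside.
#'
#' @param params an [image_sim_params()] object (illumination, offset and
#'   noise parameters are used).
#' @param n_fields number of empty-well fields (default 10).
#' @param level constant emission level of the empty well in counts.
#' @return list: `fields` (list of matrices), `dark` (noiseless dark frame),
#'   `illum` (true illumination field), `level`.
#' @export
simulate_flatfield <- function(params, n_fields = 10L, level = 1000) {
  stopifnot(inherits(params, "image_sim_params"), n_fields >= 1, level > 0)
  set.seed(params$seed)
  H <- params$field_size_px[1]; W <- params$field_size_px[2]
  illum <- illumination_field(c(H, W), params$illum_gradient_amp)
  clean <- level * illum + params$dark_offset
  fields <- lapply(seq_len(n_fields), function(i) {
    x <- as.numeric(clean)
    if (params$shot_noise) x <- stats::rpois(length(x), x)
    if (params$read_noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, params$read_noise_sd)
    matrix(round(clamp(x, 0, 65535)), H, W)
  })
  list(fields = fields, dark = matrix(params$dark_offset, H, W),
       illum = illum, level = level)
}
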