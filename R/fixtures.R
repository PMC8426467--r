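# Deterministic synthetic fixtures. These emulate the two stroma texture
# regimes — mature: fine elongated fibres in near-parallel orientation;
# immature: disorganised fibre orientation with bright oedema-like blobs —
# plus whitespace tiles and stain-shifted batches, so every processing step
# can be exercised without any real slide data. The texture model is
# band-limited oriented noise, not a biophysical fibre simulator: it gives
# the pre-processing code paths a recoverable signal, nothing more.

# internal: isotropic smoothed Gaussian noise field in [0,1]
smooth_noise <- function(size, sigma) {
  m <- matrix(stats::rnorm(size * size), size, size)
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma); k <- k / sum(k)
  p <- pad_reflect(m, radius)
  tmp <- matrix(0, size + 2 * radius, size)
  for (d in -radius:radius) {
    tmp <- tmp + k[d + radius + 1] *
      p[, (radius + 1 + d):(radius + size + d), drop = FALSE]
  }
  out <- matrix(0, size, size)
  for (d in -radius:radius) {
    out <- out + k[d + radius + 1] *
      tmp[(radius + 1 + d):(radius + size + d), , drop = FALSE]
  }
  (out - min(out)) / max(1e-12, diff(range(out)))
}

#' Generate a fibre-textured tile
#'
#' High `coherence` produces fibres running near-parallel at the requested
#' orientation (mature-like); low coherence mixes orientations isotropically
#' and adds bright blobs mimicking oedema (immature-like). The grayscale
#' texture is tinted with an H&E-like pink so colour-channel code paths are
#' exercised too. Output is a pure function of the arguments.
#'
#' @param size Tile side in pixels (>= 16; default 250).
#' @param orientation Fibre direction in degrees (0 = horizontal fibres,
#'   measured counter-clockwise from the x axis).
#' @param coherence Orientation coherence in `[0, 1]`: 1 = strictly
#'   parallel fibres, 0 = fully disorganised.
#' @param seed Integer seed.
#' @return A 3-channel [tile_image()].
#' @export
make_fiber_tile <- function(size = 250, orientation = 0, coherence = 1,
                            seed) {
  if (size < 16) {
    rlang::abort("`size` must be >= 16.", class = "histotile_value_error")
  }
  if (coherence < 0 || coherence > 1) {
    rlang::abort("`coherence` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  withr::with_seed(seed, {
    xs <- matrix(rep(seq_len(size), each = size), size, size)  # col index
    ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
    # oriented component: sum of sinusoidal bands along `orientation`,
    # frequencies in the fibre-width range, with phase jitter
    theta <- orientation * pi / 180
    u <- cos(theta) * xs + sin(theta) * ys   # along-fibre coordinate
    v <- -sin(theta) * xs + cos(theta) * ys  # across-fibre coordinate
    oriented <- matrix(0, size, size)
    for (f in stats::runif(4, 0.08, 0.25)) {
      oriented <- oriented + sin(2 * pi * f * v + stats::runif(1, 0, 2 * pi))
    }
    oriented <- oriented + 0.6 * smooth_noise(size, 1.5)
    oriented <- (oriented - min(oriented)) / diff(range(oriented))
    # disorganised component: superposed bands at random orientations
    iso <- matrix(0, size, size)
    for (i in 1:4) {
      th <- stats::runif(1, 0, pi)
      w <- -sin(th) * xs + cos(th) * ys
      iso <- iso + sin(2 * pi * stats::runif(1, 0.08, 0.25) * w +
                         stats::runif(1, 0, 2 * pi))
    }
    iso <- iso + 0.8 * smooth_noise(size, 2)
    iso <- (iso - min(iso)) / diff(range(iso))
    tex <- coherence * oriented + (1 - coherence) * iso
    # oedema-like bright blobs, stronger the less coherent the tissue
    if (coherence < 1) {
      blobs <- smooth_noise(size, size / 12)
      blob_mask <- blobs > stats::quantile(blobs, 0.85)
      tex[blob_mask] <- tex[blob_mask] + (1 - coherence) * 0.9
      # renormalise rather than clip: clipping would pile blob pixels into
      # a single gray level and put an artificial atom in the histogram
      tex <- (tex - min(tex)) / diff(range(tex))
    }
    # H&E-ish tint: dark fibres toward purple-pink, light gaps toward white;
    # a touch of per-pixel sensor noise keeps the channel histograms smooth
    n_px <- size * size
    r <- 120 + 120 * tex + stats::rnorm(n_px, 0, 1.5)
    g <- 60 + 150 * tex + stats::rnorm(n_px, 0, 1.5)
    b <- 130 + 110 * tex + stats::rnorm(n_px, 0, 1.5)
    tile_image(clip8(array(c(r, g, b), c(size, size, 3))))
  })
}

#' Orientation coherence statistic of a tile
#'
#' Summarises the gradient structure tensor of the grayscale image:
#' `dominant_orientation` is the fibre (stripe) direction in degrees and
#' `coherence` the normalised eigenvalue anisotropy
#' `(l1 - l2) / (l1 + l2)` in `[0, 1]`. Parallel-fibre textures score high,
#' disorganised ones low — a cheap stand-in classifier signal for
#' end-to-end pipeline tests.
#'
#' @param img A [tile_image()].
#' @return A one-row tibble: `dominant_orientation` (degrees in
#'   `[0, 180)`), `coherence`.
#' @export
orientation_coherence <- function(img) {
  g <- as_pixel_array(to_grayscale(img)) / 255
  H <- nrow(g); W <- ncol(g)
  gx <- (g[, c(2:W, W)] - g[, c(1, 1:(W - 1))]) / 2  # d/dcol
  gy <- (g[c(2:H, H), ] - g[c(1, 1:(H - 1)), ]) / 2  # d/drow
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  # gradient dominant direction (doubled-angle form); fibres run at 90 deg
  ang_grad <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  fibre <- (ang_grad + 90) %% 180
  tr <- jxx + jyy
  disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coh <- if (tr < 1e-12) 0 else disc / tr
  tibble::tibble(dominant_orientation = fibre, coherence = coh)
}

#' Generate a whitespace-calibration tile
#'
#' A bright (>= 240) background with a dark (<= 120) tissue-like region
#' occupying exactly the requested fraction of pixels, carved from a
#' smoothed random field so the region is blob-shaped rather than a block.
#' Under the default fixed threshold (220) the measured coverage equals
#' `coverage` to within one pixel.
#'
#' @param size Tile side in pixels.
#' @param coverage Target tissue fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A single-channel [tile_image()].
#' @export
make_whitespace_tile <- function(size = 250, coverage, seed) {
  if (coverage < 0 || coverage > 1) {
    rlang::abort("`coverage` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  withr::with_seed(seed, {
    field <- smooth_noise(size, size / 10)
    n_tissue <- round(coverage * size * size)
    px <- matrix(240 + floor(stats::runif(size * size, 0, 16)), size, size)
    if (n_tissue > 0) {
      ord <- order(field)[seq_len(n_tissue)]
      px[ord] <- 40 + floor(stats::runif(n_tissue, 0, 81))
    }
    tile_image(clip8(px))
  })
}

#' Simulate a staining batch effect
#'
#' Channel-wise affine shift `gain * v + bias`, clipped to `[0, 255]` —
#' the simplest model of the between-batch colour drift that histogram
#' matching is meant to undo.
#'
#' @param img A 3-channel [tile_image()].
#' @param gain Length-3 positive per-channel factors.
#' @param bias Length-3 per-channel offsets (gray levels).
#' @return The shifted [tile_image()].
#' @export
apply_stain_shift <- function(img, gain = c(1, 1, 1), bias = c(0, 0, 0)) {
  stopifnot(is_tile_image(img))
  if (any(gain <= 0)) {
    rlang::abort("`gain` must be positive.", class = "histotile_value_error")
  }
  img <- ensure_rgb(img)
  px <- as_pixel_array(img)
  gain <- rep_len(gain, 3); bias <- rep_len(bias, 3)
  for (ch in 1:3) px[, , ch] <- clip8(gain[ch] * px[, , ch] + bias[ch])
  rewrap(px, img)
}

#' Build a synthetic on-disk tile dataset
#'
#' Writes a `root/<class>/<patient>/<roi>/` tree of fibre tiles: mature
#' patients get high-coherence textures, immature patients low-coherence
#' ones. Patient class assignment follows `class_ratio` (fraction of
#' immature patients). Refuses to write into a non-empty root. Byte-exactly
#' reproducible from the seed.
#'
#' @param root Output directory (absent or empty).
#' @param n_patients,rois_per_patient,tiles_per_roi Counts (>= 1).
#' @param tile_size Tile side in pixels (default 250).
#' @param class_ratio Fraction of patients labelled immature (default 0.5).
#' @param seed Integer seed.
#' @return The [scan_dataset()] index of the tree just written.
#' @examples
#' \dontrun{
#' idx <- build_dataset(tempfile(), n_patients = 4, rois_per_patient = 2,
#'                      tiles_per_roi = 5, tile_size = 64, seed = 1)
#' class_counts(idx)
#' }
#' @export
build_dataset <- function(root, n_patients = 4, rois_per_patient = 2,
                          tiles_per_roi = 5, tile_size = 250,
                          class_ratio = 0.5, seed) {
  if (any(c(n_patients, rois_per_patient, tiles_per_roi) < 1)) {
    rlang::abort("Counts must be >= 1.", class = "histotile_value_error")
  }
  if (class_ratio < 0 || class_ratio > 1) {
    rlang::abort("`class_ratio` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) > 0) {
    rlang::abort(paste0("Refusing to write into non-empty directory: ", root),
                 class = "histotile_value_error")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  n_imm <- round(class_ratio * n_patients)
  classes <- c(rep("immature", n_imm), rep("mature", n_patients - n_imm))
  base_seed <- as.integer(seed) %% 100000L
  k <- 0L
  for (p in seq_len(n_patients)) {
    cl <- classes[p]
    for (r in seq_len(rois_per_patient)) {
      for (t in seq_len(tiles_per_roi)) {
        k <- k + 1L
        tile_seed <- base_seed + 13L * k
        coh <- if (cl == "mature") 0.95 else 0.15
        ori <- (base_seed + 37 * p + 11 * r) %% 180
        img <- make_fiber_tile(tile_size, orientation = ori,
                               coherence = coh, seed = tile_seed)
        dst <- file.path(root, cl, sprintf("p%02d", p), sprintf("roi%d", r),
                         sprintf("tile%03d.png", t))
        write_tile(img, dst)
      }
    }
  }
  scan_dataset(root, levels = "class/patient/roi")
}
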