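# Pixel-level augmentation operators. All operate channel-wise on 8-bit
# tiles, preserve shape and channel count, clip to [0,255], and — for the
# seeded ones — are pure functions of (input, parameters, seed).

# internal: 2-d cross-correlation with a 3x3 kernel, symmetric-reflect
# padding, per channel
convolve3 <- function(px, K) {
  one <- function(m) {
    p <- pad_reflect(m, 1L)
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      out <- out + K[dr + 2, dc + 2] *
        p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc), drop = FALSE]
    }
    out
  }
  if (length(dim(px)) == 2L) one(px)
  else {
    out <- array(0, dim(px))
    for (ch in 1:3) out[, , ch] <- one(px[, , ch])
    out
  }
}

#' Emboss a tile
#'
#' Convolves each channel with the blended kernel
#' `K = (1 - alpha) * E + alpha * M(s)` where `E` is the 3x3 identity
#' kernel and
#' `M(s) = [[-1-s, -s, 0], [-s, 1, s], [0, s, 1+s]]`
#' is the emboss matrix at strength `s` ("intensity"). `M(s)` sums to 1 for
#' every `s`, so constant regions are fixed points and mean brightness of
#' flat areas is preserved; edges along the diagonal are accentuated —
#' which is why embossing highlights the parallel fibre structure that
#' distinguishes mature from immature stroma. Borders are padded by
#' reflection to avoid halo artefacts at tile edges.
#'
#' @param img A [tile_image()].
#' @param strength Non-negative emboss intensity `s` (default 2, the
#'   setting used throughout this package's worked examples).
#' @param alpha Blend fraction in `[0, 1]` between the original (0) and the
#'   fully embossed image (1).
#' @return The embossed [tile_image()].
#' @export
emboss <- function(img, strength = 2, alpha = 1) {
  stopifnot(is_tile_image(img))
  if (alpha < 0 || alpha > 1) {
    rlang::abort("emboss: `alpha` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  if (strength < 0) {
    rlang::abort("emboss: `strength` must be >= 0.",
                 class = "histotile_value_error")
  }
  s <- strength
  M <- matrix(c(-1 - s, -s, 0,
                -s, 1, s,
                0, s, 1 + s), 3, 3, byrow = TRUE)
  E <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  K <- (1 - alpha) * E + alpha * M
  rewrap(clip8(convolve3(as_pixel_array(img), K)), img)
}

#' @rdname augment_ops
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is_tile_image(img))
  if (sigma < 0) {
    rlang::abort("gaussian_blur: `sigma` must be >= 0.",
                 class = "histotile_value_error")
  }
  if (sigma == 0) return(img)
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  px <- as_pixel_array(img)
  blur1 <- function(m) {
    p <- pad_reflect(m, radius)
    H <- nrow(m); W <- ncol(m)
    # separable: rows then columns
    tmp <- matrix(0, H + 2 * radius, W)
    for (d in -radius:radius) {
      tmp <- tmp + k[d + radius + 1] *
        p[, (radius + 1 + d):(radius + W + d), drop = FALSE]
    }
    out <- matrix(0, H, W)
    for (d in -radius:radius) {
      out <- out + k[d + radius + 1] *
        tmp[(radius + 1 + d):(radius + H + d), , drop = FALSE]
    }
    out
  }
  out <- if (length(dim(px)) == 2L) blur1(px) else {
    a <- array(0, dim(px)); for (ch in 1:3) a[, , ch] <- blur1(px[, , ch]); a
  }
  rewrap(clip8(out), img)
}

#' Pixel-level augmentation catalogue
#'
#' A representative subset of the classical augmentation operators used to
#' expand histology training sets: blur/sharpen, additive noise, contrast
#' adjustment, and pixel/channel dropout. Seeded operators give identical
#' output for identical `(input, parameters, seed)`.
#'
#' @param img A [tile_image()].
#' @param sigma Gaussian blur standard deviation in pixels (>= 0).
#' @param alpha Sharpen blend fraction in `[0, 1]`.
#' @param sd Noise standard deviation in gray levels (>= 0).
#' @param gain,bias Contrast map `gain * v + bias`, `gain > 0`.
#' @param fraction Fraction of pixels to drop (set to 0) in `[0, 1]`;
#'   each pixel drops independently with this probability.
#' @param channel Channel index 1..3 to zero out.
#' @param seed Integer seed for the stochastic operators.
#' @return The augmented [tile_image()].
#' @name augment_ops
NULL

#' @rdname augment_ops
#' @export
sharpen <- function(img, alpha) {
  stopifnot(is_tile_image(img))
  if (alpha < 0 || alpha > 1) {
    rlang::abort("sharpen: `alpha` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  E <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  S <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)  # sums to 1
  K <- (1 - alpha) * E + alpha * S
  rewrap(clip8(convolve3(as_pixel_array(img), K)), img)
}

#' @rdname augment_ops
#' @export
additive_gaussian_noise <- function(img, sd, seed) {
  stopifnot(is_tile_image(img))
  if (sd < 0) {
    rlang::abort("additive_gaussian_noise: `sd` must be >= 0.",
                 class = "histotile_value_error")
  }
  px <- as_pixel_array(img)
  noise <- withr::with_seed(seed, stats::rnorm(length(px), sd = sd))
  rewrap(clip8(px + array(noise, dim(px))), img)
}

#' @rdname augment_ops
#' @export
adjust_contrast <- function(img, gain, bias = 0) {
  stopifnot(is_tile_image(img))
  if (gain <= 0) {
    rlang::abort("adjust_contrast: `gain` must be > 0.",
                 class = "histotile_value_error")
  }
  rewrap(clip8(gain * as_pixel_array(img) + bias), img)
}

#' @rdname augment_ops
#' @export
pixel_dropout <- function(img, fraction, seed) {
  stopifnot(is_tile_image(img))
  if (fraction < 0 || fraction > 1) {
    rlang::abort("pixel_dropout: `fraction` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  px <- as_pixel_array(img)
  n_px <- prod(dim(px)[1:2])
  drop <- withr::with_seed(seed, stats::runif(n_px) < fraction)
  if (length(dim(px)) == 2L) {
    px[drop] <- 0L
  } else {
    for (ch in 1:3) {
      m <- px[, , ch]; m[drop] <- 0L; px[, , ch] <- m
    }
  }
  rewrap(px, img)
}

#' @rdname augment_ops
#' @export
channel_dropout <- function(img, channel, seed = NULL) {
  stopifnot(is_tile_image(img))
  if (n_channels(img) != 3L) {
    rlang::abort("channel_dropout: needs a 3-channel tile.",
                 class = "histotile_value_error")
  }
  if (!channel %in% 1:3) {
    rlang::abort("channel_dropout: `channel` must be 1, 2 or 3.",
                 class = "histotile_value_error")
  }
  px <- as_pixel_array(img)
  px[, , channel] <- 0L
  rewrap(px, img)
}

augmentation_registry <- function() {
  list(
    emboss = list(fn = emboss, seeded = FALSE),
    gaussian_blur = list(fn = gaussian_blur, seeded = FALSE),
    sharpen = list(fn = sharpen, seeded = FALSE),
    additive_gaussian_noise = list(fn = additive_gaussian_noise, seeded = TRUE),
    adjust_contrast = list(fn = adjust_contrast, seeded = FALSE),
    pixel_dropout = list(fn = pixel_dropout, seeded = TRUE),
    channel_dropout = list(fn = channel_dropout, seeded = FALSE)
  )
}

#' Run an ordered augmentation pipeline
#'
#' Applies a list of operator specs in order. One master seed
#' deterministically derives a sub-seed for each stochastic step, so the
#' whole pipeline is reproducible from `(input, specs, seed)`.
#'
#' @param img A [tile_image()].
#' @param specs List of specs, each `list(op = "<name>", params = list(...))`;
#'   see [augment_ops] for the operator names.
#' @param seed Master seed (required when any spec is stochastic).
#' @return The augmented [tile_image()]; an empty pipeline is the identity.
#' @export
apply_pipeline <- function(img, specs, seed = NULL) {
  stopifnot(is_tile_image(img))
  reg <- augmentation_registry()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    entry <- reg[[spec$op %||% ""]]
    if (is.null(entry)) {
      rlang::abort(paste0("Unknown augmentation op: ", spec$op),
                   class = "histotile_configuration_error")
    }
    args <- c(list(img), spec$params %||% list())
    if (entry$seeded) {
      if (is.null(seed)) {
        rlang::abort(paste0("Op '", spec$op, "' needs a pipeline seed."),
                     class = "histotile_configuration_error")
      }
      # per-op sub-seed, deterministic in (master seed, position)
      args$seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    }
    img <- do.call(entry$fn, args)
  }
  img
}

#' Augment every tile in a directory tree
#'
#' Applies an augmentation pipeline to each image under `src_root`. By
#' default outputs go to a mirrored tree under `dst_root`, named
#' `<stem>_<op suffix>.png` so each derived image names its source;
#' `in_place = TRUE` overwrites instead (explicit opt-in — the default
#' never touches source data).
#'
#' @inheritParams apply_pipeline
#' @param src_root Source directory (any nesting; structure preserved).
#' @param dst_root Output root (required unless `in_place`).
#' @param in_place Overwrite source tiles.
#' @return A tibble with columns `src`, `dst`, `status`.
#' @export
augment_directory <- function(src_root, specs, dst_root = NULL,
                              in_place = FALSE, seed = NULL) {
  stopifnot(dir.exists(src_root))
  if (!in_place && is.null(dst_root)) {
    rlang::abort("Provide `dst_root` or set `in_place = TRUE`.",
                 class = "histotile_configuration_error")
  }
  suffix <- paste(vapply(specs, function(s) s$op, character(1)),
                  collapse = "-")
  files <- list.files(src_root, recursive = TRUE, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% image_extensions]
  out_root <- if (in_place) src_root else dst_root
  rows <- purrr::map(seq_along(files), function(i) {
    f <- files[i]
    dst <- if (in_place) f else {
      rel <- rel_path(f, src_root)
      file.path(dst_root, dirname(rel),
                paste0(tools::file_path_sans_ext(basename(rel)),
                       "_", suffix, ".png"))
    }
    ok <- tryCatch({
      # per-file sub-seed; deterministic given the (sorted) file list
      fseed <- if (is.null(seed)) NULL else
        (as.integer(seed) + 104729L * i) %% .Machine$integer.max
      write_tile(apply_pipeline(read_tile(f), specs, seed = fseed), dst)
      TRUE
    }, error = function(e) FALSE)
    tibble::tibble(src = f, dst = dst,
                   status = if (ok) "augmented" else "skipped")
  })
  report <- dplyr::bind_rows(rows)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  done <- report$status == "augmented"
  write_manifest(out_root, "augment",
                 parameters = list(specs = specs, in_place = in_place),
                 actions = manifest_actions(
                   src = report$src[done],
                   action = if (in_place) "replaced" else "created",
                   dst = report$dst[done]),
                 seed = seed)
  report
}
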