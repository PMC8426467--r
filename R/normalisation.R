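#' Promote a tile to RGB
#'
#' Single-channel tiles are replicated into three identical channels so they
#' can be histogram-matched against an RGB target; RGB tiles pass through
#' unchanged.
#'
#' @param img A [tile_image()] with 1 or 3 channels.
#' @return A 3-channel [tile_image()].
#' @export
ensure_rgb <- function(img) {
  stopifnot(is_tile_image(img))
  if (n_channels(img) == 3L) return(img)
  px <- as_pixel_array(img)
  rewrap(array(rep(px, 3), dim = c(dim(px), 3L)), img)
}

#' Per-channel intensity histogram and CDF
#'
#' The cumulative distribution `F(v) = P(pixel <= v)` over the 256 gray
#' levels, computed per channel. Histogram matching compares these
#' cumulative histograms between an input and a target image.
#'
#' @param img A [tile_image()].
#' @return A `histogram_profile` tibble: columns `channel` (1..n),
#'   `value` (0..255), `count` and `cdf`; 256 rows per channel.
#' @export
channel_profile <- function(img) {
  stopifnot(is_tile_image(img))
  px <- as_pixel_array(img)
  nc <- n_channels(img)
  per_channel <- function(v) {
    counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
    tibble::tibble(value = 0:255, count = counts,
                   cdf = cumsum(counts) / length(v))
  }
  prof <- if (nc == 1L) {
    dplyr::mutate(per_channel(px), channel = 1L, .before = 1)
  } else {
    purrr::map_dfr(1:3, function(ch) {
      dplyr::mutate(per_channel(px[, , ch]), channel = ch, .before = 1)
    })
  }
  structure(prof, n_channels = nc,
            class = c("histogram_profile", class(prof)))
}

# internal: the matching lookup table for one channel.
# m(v) = min{ u : F_target(u) >= F_src(v) }, monotone non-decreasing.
match_lut <- function(src_cdf, target_cdf) {
  # findInterval over the target CDF: number of target levels with
  # F_target(u) strictly below F_src(v) equals the smallest eligible u
  lut <- findInterval(src_cdf, target_cdf, left.open = TRUE)
  pmin(lut, 255L)
}

#' Match a tile's histogram to a target profile
#'
#' Remaps each channel's pixel values by the monotone map
#' `m(v) = min(u : F_target(u) >= F_src(v))`, so the output's cumulative
#' intensity histogram tracks the target's. This is the classical
#' cumulative-histogram stain-normalisation step: it removes batch effects
#' in staining intensity while preserving the rank order of pixel values
#' (and hence the tissue architecture). It can, however, create artefactual
#' whitespace when the target has much more background than the input.
#'
#' @param src A [tile_image()]; promoted with [ensure_rgb()] if the target
#'   profile has 3 channels.
#' @param target_profile A `histogram_profile` from [channel_profile()].
#' @return The matched [tile_image()].
#' @export
histogram_match <- function(src, target_profile) {
  stopifnot(is_tile_image(src), inherits(target_profile, "histogram_profile"))
  nt <- attr(target_profile, "n_channels")
  if (sum(target_profile$count) == 0) {
    rlang::abort("Empty target profile.", class = "histotile_value_error")
  }
  if (nt == 3L && n_channels(src) == 1L) src <- ensure_rgb(src)
  if (nt == 1L && n_channels(src) == 3L) {
    rlang::abort("Cannot match an RGB tile to a single-channel profile.",
                 class = "histotile_value_error")
  }
  src_prof <- channel_profile(src)
  px <- as_pixel_array(src)
  out <- px
  for (ch in seq_len(n_channels(src))) {
    s_cdf <- src_prof$cdf[src_prof$channel == ch]
    t_cdf <- target_profile$cdf[target_profile$channel == ch]
    lut <- match_lut(s_cdf, t_cdf)
    if (n_channels(src) == 1L) out[] <- lut[px + 1L]
    else out[, , ch] <- lut[px[, , ch] + 1L]
  }
  rewrap(out, src)
}

#' Normalise a directory of tiles to one target image
#'
#' Matches every tile under `src_root` to the profile of a single fixed
#' target image — using one target for the whole cohort is what removes
#' between-slide staining batch effects. Output mirrors the source tree
#' under `dst_root`, or replaces files in place when `in_place = TRUE`.
#' Unreadable tiles are recorded as skipped and the run continues.
#'
#' @param src_root Directory of tiles (any nesting; structure preserved).
#' @param target_image Path of the image whose colour profile is the
#'   normalisation target.
#' @param dst_root Output root (required unless `in_place`).
#' @param in_place Overwrite source tiles instead of mirroring.
#' @return A tibble with columns `src`, `dst` and `status`
#'   (`"normalised"` or `"skipped"`).
#' @export
normalise_directory <- function(src_root, target_image, dst_root = NULL,
                                in_place = FALSE) {
  stopifnot(dir.exists(src_root))
  if (!in_place && is.null(dst_root)) {
    rlang::abort("Provide `dst_root` or set `in_place = TRUE`.",
                 class = "histotile_configuration_error")
  }
  target_profile <- channel_profile(ensure_rgb(read_tile(target_image)))
  files <- list.files(src_root, recursive = TRUE, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% image_extensions]
  out_root <- if (in_place) src_root else dst_root
  rows <- purrr::map(files, function(f) {
    dst <- if (in_place) f else file.path(dst_root, rel_path(f, src_root))
    ok <- tryCatch({
      img <- ensure_rgb(read_tile(f))
      write_tile(histogram_match(img, target_profile), dst)
      TRUE
    }, error = function(e) FALSE)
    tibble::tibble(src = f, dst = dst,
                   status = if (ok) "normalised" else "skipped")
  })
  report <- dplyr::bind_rows(rows)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  done <- report$status == "normalised"
  write_manifest(out_root, "normalise",
                 parameters = list(target_image = target_image,
                                   in_place = in_place),
                 actions = manifest_actions(
                   src = report$src[done],
                   action = if (in_place) "replaced" else "created",
                   dst = report$dst[done]))
  report
}

#' Sup-distance between two cumulative histograms
#'
#' Kolmogorov-style distance `max_v |F_a(v) - F_b(v)|`, per channel; the
#' natural measure of how closely a matched image tracks its target.
#'
#' @param profile_a,profile_b `histogram_profile` objects with equal
#'   channel counts.
#' @return A tibble with columns `channel` and `sup_distance`.
#' @export
cdf_distance <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "histogram_profile"),
            inherits(profile_b, "histogram_profile"),
            attr(profile_a, "n_channels") == attr(profile_b, "n_channels"))
  dplyr::inner_join(tibble::as_tibble(profile_a),
                    tibble::as_tibble(profile_b),
                    by = c("channel", "value"),
                    suffix = c("_a", "_b")) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(sup_distance = max(abs(.data$cdf_a - .data$cdf_b)),
                     .groups = "drop")
}
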