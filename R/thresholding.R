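#' Convert a tile to grayscale
#'
#' RGB tiles are reduced by the Rec. 601 luma weights
#' `0.299 R + 0.587 G + 0.114 B`, rounded half up; grayscale input is
#' returned unchanged. All masking operates on intensity, not colour:
#' H&E whitespace is bright in every channel, tissue is dark.
#'
#' @param img A [tile_image()] with 1 or 3 channels.
#' @return A single-channel [tile_image()].
#' @examples
#' to_grayscale(tile_image(array(c(255, 0, 0), c(1, 1, 3))))  # pure red -> 76
#' @export
to_grayscale <- function(img) {
  stopifnot(is_tile_image(img))
  if (n_channels(img) == 1L) return(img)
  px <- as_pixel_array(img)
  g <- 0.299 * px[, , 1, drop = FALSE] + 0.587 * px[, , 2, drop = FALSE] +
    0.114 * px[, , 3, drop = FALSE]
  dim(g) <- dim(px)[1:2]
  rewrap(clip8(g), img)
}

new_binary_mask <- function(tissue, method, threshold_used) {
  structure(tissue, method = method, threshold_used = threshold_used,
            class = c("binary_mask", class(tissue)))
}

#' @rdname binary_mask_fixed
#' @param mask A `binary_mask`.
#' @export
mask_threshold <- function(mask) attr(mask, "threshold_used")

#' @rdname binary_mask_fixed
#' @export
mask_method <- function(mask) attr(mask, "method")

#' Tissue mask by fixed global threshold
#'
#' A pixel is tissue iff its gray value is strictly below the threshold:
#' stained tissue is dark, unstained background (whitespace) is bright. The
#' default of 220 sits below typical H&E background intensity; it is a
#' parameter precisely because staining intensity varies between batches.
#'
#' @param gray A single-channel [tile_image()] (use [to_grayscale()] first
#'   for RGB tiles).
#' @param threshold Gray level in `[0, 255]`.
#' @return A `binary_mask`: logical matrix (`TRUE` = tissue) carrying the
#'   method and threshold used, readable with [mask_method()] and
#'   [mask_threshold()].
#' @export
binary_mask_fixed <- function(gray, threshold = 220) {
  check_gray(gray)
  if (threshold < 0 || threshold > 255) {
    rlang::abort("`threshold` must lie in [0, 255].",
                 class = "histotile_value_error")
  }
  new_binary_mask(as_pixel_array(gray) < threshold, "fixed", threshold)
}

#' Tissue mask by Otsu's method
#'
#' Scans all integer thresholds 0..255 and picks the one maximising the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` of the gray-level
#' histogram (ties broken toward the lowest threshold). The class below the
#' threshold — the darker pixels — is taken as tissue.
#'
#' @inheritParams binary_mask_fixed
#' @return A `binary_mask` with `mask_threshold()` set to the selected level.
#' @export
binary_mask_otsu <- function(gray) {
  check_gray(gray)
  v <- as.vector(as_pixel_array(gray))
  if (length(unique(v)) < 2L) {
    rlang::abort("Otsu thresholding needs at least 2 distinct gray values.",
                 class = "histotile_degenerate_histogram_error")
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  p <- counts / n
  levels <- 0:255
  # class 0 = {value < t}; cumulative stats up to level t-1
  w0 <- cumsum(p)                      # w0[t] = P(value <= t-1) at thr t
  s0 <- cumsum(p * levels)
  mu_total <- s0[256]
  # threshold t in 0..255 -> index t (w0[t] is mass strictly below t)
  w0_at <- c(0, w0[1:255])
  s0_at <- c(0, s0[1:255])
  w1_at <- 1 - w0_at
  valid <- w0_at > 0 & w1_at > 0
  mu0 <- s0_at / w0_at
  mu1 <- (mu_total - s0_at) / w1_at
  sigma_b <- ifelse(valid, w0_at * w1_at * (mu0 - mu1)^2, -Inf)
  t_star <- levels[which.max(sigma_b)]  # which.max takes the first maximum
  new_binary_mask(as_pixel_array(gray) < t_star, "otsu", t_star)
}

#' Tissue mask by adaptive (local mean) thresholding
#'
#' A pixel is tissue iff its value is strictly below the mean of its
#' `block x block` neighbourhood minus `offset`. Borders are padded by
#' reflection so edge pixels see a full window. Local thresholding copes
#' with uneven illumination that defeats a single global cut.
#'
#' @inheritParams binary_mask_fixed
#' @param block Odd window size >= 3 (default 51, about a fifth of a
#'   250 px tile).
#' @param offset Gray-level constant in `[-255, 255]` subtracted from the
#'   local mean (default 10); larger offsets make the mask more conservative.
#' @return A `binary_mask`; `mask_threshold()` returns the offset.
#' @export
binary_mask_adaptive <- function(gray, block = 51, offset = 10) {
  check_gray(gray)
  if (block %% 2 != 1 || block < 3) {
    rlang::abort("`block` must be an odd integer >= 3.",
                 class = "histotile_value_error")
  }
  if (offset < -255 || offset > 255) {
    rlang::abort("`offset` must lie in [-255, 255].",
                 class = "histotile_value_error")
  }
  px <- as_pixel_array(gray)
  mu <- local_mean(px, block)
  new_binary_mask(px < mu - offset, "adaptive", offset)
}

# internal: block x block local mean with symmetric (reflective) padding,
# via an integral image on the padded matrix
local_mean <- function(m, block) {
  pad <- (block - 1L) %/% 2L
  pm <- pad_reflect(m, pad)
  ii <- rbind(0, cbind(0, apply(apply(pm, 2, cumsum), 1, cumsum) |> t()))
  H <- nrow(m); W <- ncol(m)
  r1 <- seq_len(H); c1 <- seq_len(W)
  # window for output (i,j) covers padded rows i..i+block-1, cols j..j+block-1
  sums <- ii[r1 + block, c1 + block, drop = FALSE] -
    ii[r1, c1 + block, drop = FALSE] -
    ii[r1 + block, c1, drop = FALSE] +
    ii[r1, c1, drop = FALSE]
  sums / (block * block)
}

# internal: symmetric padding (edge row/col included in the reflection);
# repeats the reflection if pad exceeds the image extent
pad_reflect <- function(m, pad) {
  reflect_idx <- function(n, pad) {
    idx <- c(rev(seq_len(min(pad, n))), seq_len(n),
             rev(seq_len(n))[seq_len(min(pad, n))])
    while (length(idx) < n + 2 * pad) {  # tiny images: tile the reflection
      idx <- c(rev(idx)[seq_len(min(pad, length(idx)))], idx)
      idx <- c(idx, rev(idx)[seq_len(max(0, n + 2 * pad - length(idx)))])
    }
    idx[seq_len(n + 2 * pad)]
  }
  m[reflect_idx(nrow(m), pad), reflect_idx(ncol(m), pad), drop = FALSE]
}

check_gray <- function(img) {
  if (!is_tile_image(img) || n_channels(img) != 1L) {
    rlang::abort("Expected a single-channel tile; run to_grayscale() first.",
                 class = "histotile_value_error")
  }
  invisible(img)
}

#' Tissue coverage of a mask
#'
#' @param mask A `binary_mask` from one of the masking functions.
#' @return A one-row tibble: `coverage` (exact fraction of tissue pixels),
#'   `n_tissue`, `n_total`, `method`, `threshold_used`.
#' @export
tissue_coverage <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"), length(mask) > 0)
  n_tissue <- sum(mask)
  tibble::tibble(coverage = n_tissue / length(mask),
                 n_tissue = as.integer(n_tissue),
                 n_total = length(mask),
                 method = mask_method(mask),
                 threshold_used = mask_threshold(mask))
}

#' Estimate coverage for every tile in an index
#'
#' @param index A dataset index from [scan_dataset()].
#' @param method `"fixed"`, `"otsu"` or `"adaptive"`.
#' @param threshold,block,offset Parameters passed to the chosen masking
#'   function.
#' @return The index tibble with a `coverage` column appended.
#' @export
coverage_table <- function(index, method = c("fixed", "otsu", "adaptive"),
                           threshold = 220, block = 51, offset = 10) {
  method <- match.arg(method)
  masker <- switch(method,
    fixed = function(g) binary_mask_fixed(g, threshold),
    otsu = binary_mask_otsu,
    adaptive = function(g) binary_mask_adaptive(g, block, offset))
  cov <- purrr::map_dbl(index$path, function(p) {
    tissue_coverage(masker(to_grayscale(read_tile(p))))$coverage
  })
  dplyr::mutate(tibble::as_tibble(index), coverage = cov)
}

#' Filter tiles below a tissue-coverage cutoff
#'
#' Computes coverage for every indexed tile and deletes — or relocates,
#' preserving the directory structure — tiles whose coverage falls strictly
#' below `min_coverage`; tiles exactly at the cutoff survive. Excess
#' whitespace dilutes what a stroma classifier can learn from a tile, so
#' datasets are routinely screened this way before training. A manifest
#' listing every action is written beside the dataset root.
#'
#' @inheritParams coverage_table
#' @param min_coverage Minimum tissue fraction in `[0, 1]` a tile must
#'   reach to be kept.
#' @param action `"delete"` removes failing tiles; `"relocate"` moves them
#'   under `relocate_dir`.
#' @param relocate_dir Destination root for relocated tiles (required for
#'   `action = "relocate"`).
#' @return A `filter_report`: the per-tile coverage tibble with an `action`
#'   column (`"kept"`, `"deleted"` or `"moved"`); per-class totals via
#'   [summary()].
#' @export
filter_tiles <- function(index, method = c("fixed", "otsu", "adaptive"),
                         min_coverage = 0.8, action = c("delete", "relocate"),
                         relocate_dir = NULL,
                         threshold = 220, block = 51, offset = 10) {
  method <- match.arg(method)
  action <- match.arg(action)
  if (min_coverage < 0 || min_coverage > 1) {
    rlang::abort("`min_coverage` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  if (action == "relocate" && is.null(relocate_dir)) {
    rlang::abort("`relocate` requires `relocate_dir`.",
                 class = "histotile_configuration_error")
  }
  tab <- coverage_table(index, method, threshold, block, offset)
  fails <- tab$coverage < min_coverage
  root <- dataset_root(index)
  acts <- character(nrow(tab))
  dsts <- character(nrow(tab))
  for (i in which(fails)) {
    if (action == "delete") {
      unlink(tab$path[i])
      acts[i] <- "deleted"; dsts[i] <- ""
    } else {
      dst <- file.path(relocate_dir, rel_path(tab$path[i], root))
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      file.rename(tab$path[i], dst)
      acts[i] <- "moved"; dsts[i] <- dst
    }
  }
  acts[!fails] <- "kept"
  tab$action <- acts
  write_manifest(root, "threshold",
                 parameters = list(method = method,
                                   min_coverage = min_coverage,
                                   threshold = threshold, block = block,
                                   offset = offset, action = action),
                 actions = manifest_actions(src = tab$path[fails],
                                            action = acts[fails],
                                            dst = dsts[fails]))
  structure(tab, min_coverage = min_coverage,
            class = c("filter_report", class(tab)))
}

#' @export
summary.filter_report <- function(object, ...) {
  tibble::as_tibble(object) |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(kept = sum(.data$action == "kept"),
                     removed = sum(.data$action != "kept"),
                     scanned = dplyr::n(), .groups = "drop")
}

#' Coverage histogram for a filter run
#'
#' @param object A `filter_report` from [filter_tiles()].
#' @param ... Unused.
#' @return A ggplot: per-class coverage histogram with the cutoff marked.
#' @export
autoplot.filter_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$coverage, fill = .data$class_label)) +
    ggplot2::geom_histogram(bins = 20, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = attr(object, "min_coverage"),
                        linetype = "dashed") +
    ggplot2::labs(x = "estimated tissue coverage", y = "tiles",
                  fill = "class") +
    ggplot2::theme_minimal()
}
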