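#' In-memory 8-bit image tile
#'
#' A `tile_image` is an integer array of pixel values in `[0, 255]`, either
#' `height x width` (single channel) or `height x width x 3` (RGB), carrying
#' the path it was read from as provenance. It is the unit every processing
#' step in the package operates on; the default tile geometry throughout is
#' 250 x 250 px, the size routinely fed to patch-based CNNs.
#'
#' @param pixels Numeric matrix or 3-d array with values in `[0, 255]`.
#'   A third dimension, when present, must have extent 3.
#' @param source_path Optional provenance: the file the pixels came from
#'   (`""` for images built in memory).
#' @return A `tile_image` object.
#' @examples
#' img <- tile_image(matrix(0:249, 250, 250) %% 256)
#' dim(img)
#' @export
tile_image <- function(pixels, source_path = "") {
  if (!is.numeric(pixels)) {
    rlang::abort("`pixels` must be numeric.", class = "histotile_value_error")
  }
  if (is.null(dim(pixels))) {
    rlang::abort("`pixels` must be a matrix or 3-d array.",
                 class = "histotile_value_error")
  }
  nd <- length(dim(pixels))
  if (!nd %in% c(2L, 3L)) {
    rlang::abort("`pixels` must have 2 or 3 dimensions.",
                 class = "histotile_value_error")
  }
  if (nd == 3L && dim(pixels)[3] == 1L) {
    # degenerate single-channel cube collapses to a matrix
    dim(pixels) <- dim(pixels)[1:2]
    nd <- 2L
  }
  if (nd == 3L && dim(pixels)[3] != 3L) {
    rlang::abort("Channel count must be 1 or 3.",
                 class = "histotile_value_error")
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    rlang::abort("Image height and width must be >= 1.",
                 class = "histotile_value_error")
  }
  v <- as.vector(pixels)
  if (anyNA(v) || min(v) < 0 || max(v) > 255) {
    rlang::abort("Pixel values must lie in [0, 255] with no missing values.",
                 class = "histotile_value_error")
  }
  # drop any stray attributes (e.g. decoder metadata), keep only dim
  pixels <- array(as.integer(pixels), dim = dim(pixels))
  structure(pixels, source_path = as.character(source_path),
            class = c("tile_image", class(pixels)))
}

#' @export
print.tile_image <- function(x, ...) {
  d <- dim(x)
  ch <- if (length(d) == 3L) d[3] else 1L
  src <- attr(x, "source_path")
  cat(sprintf("<tile_image> %d x %d px, %d channel%s%s\n",
              d[1], d[2], ch, if (ch > 1) "s" else "",
              if (nzchar(src)) paste0(", from ", src) else ""))
  invisible(x)
}

#' @rdname tile_image
#' @param x Object to test or coerce.
#' @export
is_tile_image <- function(x) inherits(x, "tile_image")

#' Number of channels of a tile
#'
#' @param img A [tile_image()].
#' @return 1 for grayscale, 3 for RGB.
#' @export
n_channels <- function(img) {
  if (length(dim(img)) == 3L) dim(img)[3] else 1L
}

# internal: strip class/attrs down to a bare integer array
as_pixel_array <- function(img) {
  a <- unclass(img)
  attr(a, "source_path") <- NULL
  a
}

# internal: rebuild a tile_image around transformed pixels, keeping provenance
rewrap <- function(pixels, template) {
  tile_image(pixels, source_path = attr(template, "source_path") %||% "")
}

# internal: clip to the 8-bit range and round half up (consistent across
# platforms; base round() is banker's)
clip8 <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}

#' Display a tile as a raster
#'
#' @param object A [tile_image()].
#' @param ... Unused.
#' @return A ggplot object rendering the tile pixels.
#' @export
autoplot.tile_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  if (n_channels(object) == 3L) {
    df$fill <- grDevices::rgb(object[, , 1] / 255, object[, , 2] / 255,
                              object[, , 3] / 255)
  } else {
    g <- as_pixel_array(object) / 255
    df$fill <- grDevices::gray(as.vector(g))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
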