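#' Read an image tile from disk
#'
#' Reads an 8-bit PNG or JPEG into a [tile_image()]. Grayscale files yield a
#' single channel, colour files three; an alpha channel, if present, is
#' discarded. 16-bit PNGs are rejected rather than silently rescaled.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A [tile_image()] with `source_path` set to `path`.
#' @seealso [write_tile()]
#' @export
read_tile <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such image file: ", path),
                 class = "histotile_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) {
                      rlang::abort(paste0("Unreadable PNG: ", path),
                                   class = "histotile_format_error",
                                   parent = e)
                    })
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      rlang::abort(paste0("16-bit PNG not supported: ", path),
                   class = "histotile_format_error")
    }
    px <- raw
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      rlang::abort("JPEG support requires the EBImage package.",
                   class = "histotile_format_error")
    }
    eb <- tryCatch(EBImage::readImage(path),
                   error = function(e) {
                     rlang::abort(paste0("Unreadable JPEG: ", path),
                                  class = "histotile_format_error",
                                  parent = e)
                   })
    # EBImage stores x (columns) first; transpose back to row-major
    a <- EBImage::imageData(eb)
    px <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  } else {
    rlang::abort(paste0("Unsupported image format '.", ext, "': ", path),
                 class = "histotile_format_error")
  }
  d <- dim(px)
  if (length(d) == 3L && d[3] %in% c(2L, 4L)) {
    # grayscale+alpha or RGBA: drop alpha
    px <- px[, , seq_len(d[3] - 1L), drop = FALSE]
    d <- dim(px)
  }
  if (length(d) == 3L && d[3] == 1L) px <- px[, , 1L, drop = TRUE]
  tile_image(clip8(px * 255), source_path = path)
}

#' Write an image tile to disk
#'
#' PNG output is lossless: re-reading reproduces the pixel array exactly.
#' JPEG is lossy and must be requested explicitly through the file extension.
#'
#' @param img A [tile_image()].
#' @param path Destination path ending in `.png`, `.jpg` or `.jpeg`;
#'   parent directories are created as needed.
#' @param quality JPEG quality in `(0, 1]`; ignored for PNG.
#' @return `path`, invisibly usable in pipes.
#' @export
write_tile <- function(img, path, quality = 0.95) {
  stopifnot(is_tile_image(img))
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  norm <- as_pixel_array(img) / 255
  if (ext == "png") {
    png::writePNG(norm, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      rlang::abort("JPEG support requires the EBImage package.",
                   class = "histotile_format_error")
    }
    a <- if (length(dim(norm)) == 2L) t(norm) else aperm(norm, c(2, 1, 3))
    EBImage::writeImage(EBImage::Image(a,
                                       colormode = if (length(dim(norm)) == 3L) "Color" else "Grayscale"),
                        path, quality = round(quality * 100))
  } else {
    rlang::abort(paste0("Unsupported output format '.", ext, "': ", path),
                 class = "histotile_format_error")
  }
  if (!file.exists(path)) {
    rlang::abort(paste0("Failed to write: ", path), class = "histotile_io_error")
  }
  path
}

image_extensions <- c("png", "jpg", "jpeg")

#' Coordinate-stamped patch file name
#'
#' Patches cut from a larger image are named `<stem>_r<row>_c<col>` with
#' 0-based grid indices (row counts down from the top, col right from the
#' left), so every patch can be traced back to its position in the source.
#' The mapping is injective over `(stem, row, col)`.
#'
#' @param stem Source file name without extension.
#' @param row,col Non-negative 0-based patch grid indices.
#' @return The patch name stem.
#' @examples
#' make_patch_name("slideA", 0, 0)
#' @export
make_patch_name <- function(stem, row, col) {
  if (any(row < 0) || any(col < 0)) {
    rlang::abort("Patch indices must be non-negative.",
                 class = "histotile_value_error")
  }
  sprintf("%s_r%d_c%d", stem, as.integer(row), as.integer(col))
}

#' Augmented-tile file name
#'
#' Balancing and augmentation never overwrite source tiles; new images carry
#' the stem of the file they derive from plus a transform code, preserving
#' the audit trail from any derived image back to its source.
#'
#' @param stem Source file name without extension.
#' @param transform A dihedral transform code (see [dihedral_codes()]);
#'   the identity produces no new file and is rejected.
#' @return The augmented name stem `<stem>_aug-<code>`.
#' @examples
#' make_augmented_name("t1", "r90")
#' @export
make_augmented_name <- function(stem, transform) {
  transform <- as.character(transform)
  if (any(transform == "identity")) {
    rlang::abort("The identity transform produces no new file.",
                 class = "histotile_value_error")
  }
  bad <- setdiff(transform, setdiff(dihedral_codes(), "identity"))
  if (length(bad)) {
    rlang::abort(paste0("Unknown transform code: ", paste(bad, collapse = ", ")),
                 class = "histotile_value_error")
  }
  paste0(stem, "_aug-", transform)
}

#' Replicate a directory skeleton
#'
#' Creates, under `dst_root`, every class/patient/ROI directory present in a
#' scanned dataset so that processed tiles land at the same relative paths as
#' their sources.
#'
#' @param index A dataset index from [scan_dataset()].
#' @param dst_root Destination root; must not equal or sit inside the
#'   index root.
#' @return A tibble with columns `src` and `dst` mapping each indexed file
#'   to its destination path.
#' @export
mirror_tree <- function(index, dst_root) {
  src_root <- dataset_root(index)
  ns <- normalizePath(src_root, mustWork = TRUE)
  nd <- normalizePath(dst_root, mustWork = FALSE)
  if (identical(ns, nd) || startsWith(paste0(nd, "/"), paste0(ns, "/"))) {
    rlang::abort("`dst_root` must lie outside the source root.",
                 class = "histotile_nesting_error")
  }
  rel <- rel_path(index$path, src_root)
  dst <- file.path(dst_root, rel)
  for (d in unique(dirname(dst))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  tibble::tibble(src = index$path, dst = dst)
}

# internal: path of `paths` relative to `root`
rel_path <- function(paths, root) {
  root <- normalizePath(root, mustWork = TRUE)
  paths <- normalizePath(paths, mustWork = FALSE)
  sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", root), "/?"), "",
      paths)
}
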