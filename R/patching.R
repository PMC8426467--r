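#' Patch-grid specification
#'
#' CNNs need input tiles of consistent dimensions, so larger images are cut
#' on a fixed grid anchored at the top-left pixel. The default stride equals
#' the patch size (non-overlapping); an explicit smaller stride yields
#' overlapping patches. Partial tiles at the right/bottom edge are dropped by
#' default — a CNN cannot use ragged tiles, and padding would invent pixels.
#'
#' @param height,width Patch dimensions in pixels (>= 1).
#' @param stride_v,stride_h Grid strides in pixels; default = patch size.
#' @param drop_partial Drop patches that would overrun the image edge
#'   (default `TRUE`).
#' @return A `patch_grid` list.
#' @export
patch_grid <- function(height = 250, width = height,
                       stride_v = height, stride_h = width,
                       drop_partial = TRUE) {
  if (any(c(height, width, stride_v, stride_h) < 1)) {
    rlang::abort("Patch dimensions and strides must be >= 1.",
                 class = "histotile_value_error")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 stride_v = as.integer(stride_v),
                 stride_h = as.integer(stride_h),
                 drop_partial = isTRUE(drop_partial)),
            class = "patch_grid")
}

#' Cut an image into grid patches
#'
#' Patches are exact crops placed at offsets
#' `(row * stride_v, col * stride_h)` from the top-left pixel, enumerated
#' row-major with 0-based indices — the indices stamped into patch file
#' names by [make_patch_name()]. The patch set is a pure function of the
#' image and the grid.
#'
#' @param img A [tile_image()].
#' @param grid A [patch_grid()].
#' @return A tibble with columns `row`, `col` (0-based grid indices) and
#'   `patch` (list column of [tile_image()]s). Empty, with a warning, when
#'   the patch does not fit the image.
#' @examples
#' img <- tile_image(matrix(seq_len(16) * 10, 4, 4))
#' extract_patches(img, patch_grid(2, 2))
#' @export
extract_patches <- function(img, grid) {
  stopifnot(is_tile_image(img), inherits(grid, "patch_grid"))
  H <- nrow(img); W <- ncol(img)
  if (grid$drop_partial && (grid$height > H || grid$width > W)) {
    rlang::warn("Patch larger than image; no patches extracted.")
    return(tibble::tibble(row = integer(), col = integer(), patch = list()))
  }
  max_r0 <- if (grid$drop_partial) H - grid$height else H - 1L
  max_c0 <- if (grid$drop_partial) W - grid$width else W - 1L
  rows0 <- seq(0L, max_r0, by = grid$stride_v)
  cols0 <- seq(0L, max_c0, by = grid$stride_h)
  out <- tidyr::expand_grid(row = seq_along(rows0) - 1L,
                            col = seq_along(cols0) - 1L)
  px <- as_pixel_array(img)
  out$patch <- purrr::pmap(out, function(row, col) {
    r0 <- rows0[row + 1L]; c0 <- cols0[col + 1L]
    ri <- (r0 + 1L):min(r0 + grid$height, H)
    ci <- (c0 + 1L):min(c0 + grid$width, W)
    sub <- if (length(dim(px)) == 3L) px[ri, ci, , drop = FALSE]
           else px[ri, ci, drop = FALSE]
    tile_image(sub, source_path = attr(img, "source_path"))
  })
  out
}

#' Patch every image in a directory tree
#'
#' Block-processes all images under `src_root`, mirroring its directory
#' structure under `dst_root` and saving each patch as a PNG named with
#' [make_patch_name()]. A manifest recording every file created is written
#' to `dst_root`. Rerunning on unchanged inputs reproduces the same file
#' set (the operation is deterministic).
#'
#' @param src_root Directory containing source images (scanned recursively;
#'   any nesting depth is allowed and preserved).
#' @param dst_root Output directory, outside `src_root`.
#' @param grid A [patch_grid()].
#' @return A `patch_report` tibble: one row per source image with its patch
#'   count; the grid and totals (`n_source_images`, `n_patches_written`)
#'   are attached as attributes.
#' @export
patch_directory <- function(src_root, dst_root, grid = patch_grid()) {
  stopifnot(dir.exists(src_root))
  ns <- normalizePath(src_root)
  nd <- normalizePath(dst_root, mustWork = FALSE)
  if (identical(ns, nd) || startsWith(paste0(nd, "/"), paste0(ns, "/"))) {
    rlang::abort("`dst_root` must lie outside `src_root`.",
                 class = "histotile_nesting_error")
  }
  files <- list.files(src_root, recursive = TRUE, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% image_extensions]
  if (length(files) == 0) {
    rlang::abort(paste0("No images under ", src_root),
                 class = "histotile_empty_index_error")
  }
  dir.create(dst_root, recursive = TRUE, showWarnings = FALSE)
  actions <- list()
  report <- purrr::map(files, function(f) {
    img <- read_tile(f)
    patches <- extract_patches(img, grid)
    rel_dir <- dirname(rel_path(f, src_root))
    out_dir <- if (rel_dir == ".") dst_root else file.path(dst_root, rel_dir)
    stem <- tools::file_path_sans_ext(basename(f))
    written <- purrr::pmap_chr(patches, function(row, col, patch) {
      dst <- file.path(out_dir, paste0(make_patch_name(stem, row, col), ".png"))
      if (file.exists(dst)) {
        rlang::abort(paste0("Patch name collision: ", dst),
                     class = "histotile_io_error")
      }
      write_tile(patch, dst)
    })
    actions[[f]] <<- manifest_actions(src = rep(f, length(written)),
                                      action = "created", dst = written)
    tibble::tibble(source = f, n_patches = nrow(patches))
  }) |> dplyr::bind_rows()
  write_manifest(dst_root, "patch",
                 parameters = unclass(grid),
                 actions = dplyr::bind_rows(actions))
  structure(report,
            grid = grid,
            n_source_images = length(files),
            n_patches_written = sum(report$n_patches),
            class = c("patch_report", class(report)))
}
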