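#' Dihedral transforms of the square
#'
#' The eight axis-aligned symmetries — identity, clockwise rotations by
#' 90/180/270 degrees, and a horizontal mirror optionally followed by one
#' rotation — form the dihedral group D4. The 7 non-identity elements are
#' the augmentation set used for class balancing: they permute pixels
#' exactly, with no interpolation, so no image information is invented.
#'
#' @return Character vector of the 8 transform codes, identity first.
#' @examples
#' dihedral_codes()
#' @export
dihedral_codes <- function() {
  c("identity", "r90", "r180", "r270", "m", "mr90", "mr180", "mr270")
}

#' Apply a dihedral transform to a tile
#'
#' `m` mirrors left-right; in composite codes the mirror is applied first,
#' then the clockwise rotation. `r90`/`r270` swap height and width on
#' non-square tiles.
#'
#' @param img A [tile_image()].
#' @param code One of [dihedral_codes()].
#' @return The transformed [tile_image()].
#' @examples
#' dihedral_apply(tile_image(matrix(1:4, 2, 2, byrow = TRUE)), "r90")
#' @export
dihedral_apply <- function(img, code) {
  stopifnot(is_tile_image(img))
  code <- match.arg(code, dihedral_codes())
  px <- as_pixel_array(img)
  rot90cw <- function(a) {  # clockwise quarter turn, any channel count
    if (length(dim(a)) == 2L) t(a[nrow(a):1, , drop = FALSE])
    else aperm(a[nrow(a):1, , , drop = FALSE], c(2, 1, 3))
  }
  mirror_lr <- function(a) {
    if (length(dim(a)) == 2L) a[, ncol(a):1, drop = FALSE]
    else a[, ncol(a):1, , drop = FALSE]
  }
  if (startsWith(code, "m")) {
    px <- mirror_lr(px)
  }
  rot <- sub("^m", "", code)
  turns <- if (rot %in% c("", "identity")) 0L
           else c(r90 = 1L, r180 = 2L, r270 = 3L)[[rot]]
  for (i in seq_len(turns)) px <- rot90cw(px)
  rewrap(px, img)
}

#' All seven augmentations of a tile
#'
#' Applies every non-identity dihedral transform. For a generic asymmetric
#' tile the seven outputs are pairwise distinct and all differ from the
#' source ("up to 7 unique images"); symmetric tiles collapse some of them.
#'
#' @param img A [tile_image()].
#' @return A tibble with columns `transform` (code) and `image`
#'   (list of [tile_image()]).
#' @export
enumerate_augmentations <- function(img) {
  codes <- setdiff(dihedral_codes(), "identity")
  tibble::tibble(transform = codes,
                 image = purrr::map(codes, ~dihedral_apply(img, .x)))
}

#' The one-eighth balancing precondition
#'
#' Augmentation-based balancing requires that no class hold fewer than one
#' eighth of the samples of the largest class: each source tile has only 7
#' distinct augmentations, so a deficit larger than 7x the class size could
#' not be met without duplicating images.
#'
#' @param class_counts Named integer vector or a [class_counts()] tibble.
#' @return A list: `pass` (logical) and `offending` (class names that fall
#'   below the bound; empty when passing).
#' @examples
#' check_eighth_rule(c(A = 800, B = 100))$pass   # boundary: exactly 1/8 passes
#' check_eighth_rule(c(A = 900, B = 100))$pass
#' @export
check_eighth_rule <- function(class_counts) {
  counts <- as_count_vector(class_counts)
  if (length(counts) < 2) {
    rlang::abort("Need at least 2 classes.", class = "histotile_value_error")
  }
  if (any(counts < 1)) {
    rlang::abort("Every class must contain at least one image.",
                 class = "histotile_value_error")
  }
  bound <- max(counts) / 8
  offending <- names(counts)[counts < bound]
  list(pass = length(offending) == 0, offending = offending)
}

as_count_vector <- function(class_counts) {
  if (is.data.frame(class_counts)) {
    stats::setNames(as.integer(class_counts$n), class_counts$class_label)
  } else {
    stats::setNames(as.integer(class_counts), names(class_counts))
  }
}

#' Plan a class-balancing run
#'
#' Decides, per class, which tiles to augment or remove so that all classes
#' end at the same size: the largest (`to_max`), smallest (`to_min`) or
#' rounded mean (`to_mean`; classes above the target reduce, below augment).
#' Deficits are filled in rounds of sampling sources without replacement,
#' drawing for each selected source a dihedral transform not yet used for
#' it — so no (source, transform) pair is ever planned twice, and the
#' one-eighth precondition guarantees at most 7 rounds suffice. The plan is
#' a deterministic function of the index, mode and seed.
#'
#' @param index A dataset index from [scan_dataset()].
#' @param mode `"to_max"`, `"to_min"` or `"to_mean"`.
#' @param seed Integer seed; record it to make the run reproducible.
#' @return A `balance_plan`: tibble with one row per planned action —
#'   columns `class_label`, `op` (`"create"` or `"remove"`), `path`, and
#'   `transform` (`NA` for removals) — with the per-class targets in
#'   attribute `targets`.
#' @export
plan_balance <- function(index, mode = c("to_max", "to_min", "to_mean"),
                         seed) {
  mode <- match.arg(mode)
  counts <- as_count_vector(class_counts(index))
  targets <- switch(mode,
                    to_max = rep(max(counts), length(counts)),
                    to_min = rep(min(counts), length(counts)),
                    to_mean = rep(floor(mean(counts) + 0.5), length(counts)))
  names(targets) <- names(counts)
  if (any(targets > counts)) {
    chk <- check_eighth_rule(counts)
    if (!chk$pass) {
      rlang::abort(paste0(
        "Augmentation balancing requires that no class contains less than ",
        "one eighth of the samples of the largest class; offending: ",
        paste(chk$offending, collapse = ", ")),
        class = "histotile_precondition_error")
    }
    if (any(targets - counts > 7 * counts)) {
      rlang::abort("Deficit exceeds 7 augmentations per source image.",
                   class = "histotile_precondition_error")
    }
  }
  aug_codes <- setdiff(dihedral_codes(), "identity")
  rows <- withr::with_seed(seed, {
    purrr::map(names(counts), function(cl) {
      paths <- index$path[index$class_label == cl]
      delta <- targets[[cl]] - counts[[cl]]
      if (delta == 0) return(NULL)
      if (delta < 0) {
        drop <- sample(paths, -delta)
        return(tibble::tibble(class_label = cl, op = "remove", path = drop,
                              transform = NA_character_))
      }
      used <- stats::setNames(vector("list", length(paths)), paths)
      picked_path <- character(delta)
      picked_tf <- character(delta)
      k <- 0L
      while (k < delta) {
        take <- min(delta - k, length(paths))
        srcs <- sample(paths, take)  # one round: without replacement
        for (s in srcs) {
          avail <- setdiff(aug_codes, used[[s]])
          tf <- if (length(avail) == 1) avail else sample(avail, 1)
          used[[s]] <- c(used[[s]], tf)
          k <- k + 1L
          picked_path[k] <- s
          picked_tf[k] <- tf
        }
      }
      tibble::tibble(class_label = cl, op = "create", path = picked_path,
                     transform = picked_tf)
    })
  })
  plan <- dplyr::bind_rows(rows)
  if (nrow(plan) == 0) {
    plan <- tibble::tibble(class_label = character(), op = character(),
                           path = character(), transform = character())
  }
  structure(plan, targets = targets, mode = mode, seed = as.integer(seed),
            root = dataset_root(index), levels = dataset_levels(index),
            class = c("balance_plan", class(plan)))
}

#' Execute a balance plan on disk
#'
#' Created tiles are written beside their source, named with
#' [make_augmented_name()]; removed tiles are moved into a
#' `"Removed Images"` directory at the dataset root (structure preserved)
#' unless `hard_delete` is set. After execution a rescan shows every class
#' at its target size. The manifest records the seed and every file action.
#'
#' @param plan A `balance_plan` from [plan_balance()].
#' @param removed_dir_name Directory (under the dataset root) collecting
#'   removed tiles; default `"Removed Images"`.
#' @param hard_delete Permanently delete instead of relocating removals.
#' @return A `balance_report` tibble: per-class before/target counts plus
#'   numbers of files created and removed.
#' @export
execute_balance <- function(plan, removed_dir_name = "Removed Images",
                            hard_delete = FALSE) {
  stopifnot(inherits(plan, "balance_plan"))
  root <- attr(plan, "root")
  targets <- attr(plan, "targets")
  actions <- list()
  creates <- plan[plan$op == "create", , drop = FALSE]
  if (nrow(creates)) {
    key <- paste(creates$path, creates$transform)
    if (anyDuplicated(key)) {
      rlang::abort("Duplicate (source, transform) pair in plan.",
                   class = "histotile_io_error")
    }
    for (i in seq_len(nrow(creates))) {
      src <- creates$path[i]
      stem <- tools::file_path_sans_ext(basename(src))
      dst <- file.path(dirname(src),
                       paste0(make_augmented_name(stem, creates$transform[i]),
                              ".png"))
      if (file.exists(dst)) {
        rlang::abort(paste0("Augmented name collision: ", dst),
                     class = "histotile_io_error")
      }
      write_tile(dihedral_apply(read_tile(src), creates$transform[i]), dst)
      actions[[length(actions) + 1L]] <-
        manifest_actions(src, "created", dst)
    }
  }
  removes <- plan[plan$op == "remove", , drop = FALSE]
  for (i in seq_len(nrow(removes))) {
    src <- removes$path[i]
    if (hard_delete) {
      unlink(src)
      actions[[length(actions) + 1L]] <- manifest_actions(src, "deleted", "")
    } else {
      dst <- file.path(root, removed_dir_name, rel_path(src, root))
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      file.rename(src, dst)
      actions[[length(actions) + 1L]] <- manifest_actions(src, "moved", dst)
    }
  }
  write_manifest(root, "balance",
                 parameters = list(mode = attr(plan, "mode"),
                                   removed_dir_name = removed_dir_name,
                                   hard_delete = hard_delete),
                 actions = dplyr::bind_rows(actions),
                 seed = attr(plan, "seed"))
  created <- table(factor(creates$class_label, levels = names(targets)))
  removed <- table(factor(removes$class_label, levels = names(targets)))
  report <- tibble::tibble(class_label = names(targets),
                           target = as.integer(targets),
                           n_created = as.integer(created),
                           n_removed = as.integer(removed)) |>
    dplyr::mutate(before = .data$target - .data$n_created + .data$n_removed) |>
    dplyr::relocate("class_label", "before", "target")
  structure(report, seed = attr(plan, "seed"), mode = attr(plan, "mode"),
            class = c("balance_report", class(report)))
}

#' Balance a dataset in one call
#'
#' Convenience wrapper: [plan_balance()] then [execute_balance()].
#'
#' @inheritParams plan_balance
#' @inheritParams execute_balance
#' @return The `balance_report` from [execute_balance()].
#' @export
balance_dataset <- function(index, mode = c("to_max", "to_min", "to_mean"),
                            seed, removed_dir_name = "Removed Images",
                            hard_delete = FALSE) {
  plan <- plan_balance(index, mode, seed = seed)
  execute_balance(plan, removed_dir_name = removed_dir_name,
                  hard_delete = hard_delete)
}
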