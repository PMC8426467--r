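#' Scan a tile directory tree into a dataset index
#'
#' Tiles are expected on disk as `root/<class>/<patient>/<tile>` or
#' `root/<class>/<patient>/<roi>/<tile>`: one directory per image class at
#' the top, one per patient below it, optionally one per annotated region of
#' interest (ROI). The index is the tabular handle every directory-level
#' operation takes: one row per image file, with its class, patient, ROI and
#' name stem. Non-image files are ignored.
#'
#' @param root Dataset root directory.
#' @param levels Directory layout: `"class/patient"` or `"class/patient/roi"`.
#' @return A tibble of class `dataset_index` with columns `path`,
#'   `class_label`, `patient_id`, `roi_id` (`""` when absent) and `stem`,
#'   plus the root stored as an attribute (see [dataset_root()]).
#' @examples
#' \dontrun{
#' scan_dataset("tiles", levels = "class/patient/roi") |> class_counts()
#' }
#' @export
scan_dataset <- function(root, levels = c("class/patient", "class/patient/roi")) {
  levels <- match.arg(levels)
  if (!dir.exists(root)) {
    rlang::abort(paste0("No such directory: ", root),
                 class = "histotile_value_error")
  }
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% image_extensions]
  depth <- if (levels == "class/patient") 3L else 4L
  rel <- rel_path(files, root)
  parts <- strsplit(rel, "/", fixed = TRUE)
  keep <- lengths(parts) == depth
  files <- files[keep]
  parts <- parts[keep]
  if (length(files) == 0) {
    rlang::abort(paste0("No image files found under ", root,
                        " at layout ", levels),
                 class = "histotile_empty_index_error")
  }
  idx <- tibble::tibble(
    path = files,
    class_label = purrr::map_chr(parts, 1),
    patient_id = purrr::map_chr(parts, 2),
    roi_id = if (depth == 4L) purrr::map_chr(parts, 3) else "",
    stem = tools::file_path_sans_ext(basename(files))
  )
  idx <- dplyr::arrange(idx, .data$class_label, .data$patient_id,
                        .data$roi_id, .data$stem)
  new_dataset_index(idx, root = root, levels = levels)
}

new_dataset_index <- function(tbl, root, levels) {
  structure(tbl, root = normalizePath(root),
            levels = levels,
            class = c("dataset_index", class(tbl)))
}

#' @rdname scan_dataset
#' @param index A `dataset_index`.
#' @export
dataset_root <- function(index) attr(index, "root")

#' @rdname scan_dataset
#' @export
dataset_levels <- function(index) attr(index, "levels") %||% "class/patient"

#' Per-class tile counts
#'
#' @param index A dataset index from [scan_dataset()].
#' @return A tibble with columns `class_label` and `n`.
#' @export
class_counts <- function(index) {
  dplyr::count(tibble::as_tibble(index), .data$class_label)
}

#' Split a dataset by patient
#'
#' Assigns whole patients to train/test/validation so that a heterogeneous
#' patient never straddles two sets (a CNN must not "recognise" a patient
#' between training and validation). Test and validation receive
#' `floor(fraction * n_patients)` patients each; the remainder goes to
#' train, so training is never starved by rounding. The assignment is a
#' deterministic function of the seed.
#'
#' @param index A dataset index from [scan_dataset()].
#' @param fractions Length-3 numeric `(train, test, validation)`, positive,
#'   summing to 1.
#' @param seed Integer seed controlling the patient shuffle.
#' @return A named list of three `dataset_index` tibbles:
#'   `train`, `test`, `validation`.
#' @examples
#' \dontrun{
#' splits <- scan_dataset("tiles") |> split_by_patient(c(0.7, 0.15, 0.15), seed = 1)
#' }
#' @export
split_by_patient <- function(index, fractions = c(0.70, 0.15, 0.15), seed) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    rlang::abort("`fractions` must be 3 positive numbers summing to 1.",
                 class = "histotile_value_error")
  }
  patients <- sort(unique(index$patient_id))
  n <- length(patients)
  if (n < 3) {
    rlang::abort("Need at least 3 patients to split.",
                 class = "histotile_value_error")
  }
  n_test <- floor(fractions[2] * n)
  n_val <- floor(fractions[3] * n)
  shuffled <- withr::with_seed(seed, sample(patients))
  assign <- rep("train", n)
  if (n_test > 0) assign[seq_len(n_test)] <- "test"
  if (n_val > 0) assign[n_test + seq_len(n_val)] <- "validation"
  names(assign) <- shuffled
  out <- lapply(c(train = "train", test = "test", validation = "validation"),
                function(s) {
    sub <- index[index$patient_id %in% names(assign)[assign == s], ,
                 drop = FALSE]
    new_dataset_index(tibble::as_tibble(sub), root = dataset_root(index),
                      levels = dataset_levels(index))
  })
  stopifnot(sum(vapply(out, function(i) length(unique(i$patient_id)),
                       integer(1))) == n)
  out
}
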