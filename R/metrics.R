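# Evaluation layer: tile probability -> class, tile -> ROI -> patient
# majority voting, confusion-matrix metrics, rank AUC, exact binomial CIs
# and Fleiss' kappa. The positive class is "immature" throughout, matching
# the convention that a CNN emits P(immature) and that immature stroma is
# the prognostically adverse finding.

stroma_levels <- c("mature", "immature")

check_labels <- function(x, arg) {
  bad <- setdiff(unique(as.character(x)), stroma_levels)
  if (length(bad)) {
    rlang::abort(paste0("`", arg, "` must be 'mature' or 'immature'; got: ",
                        paste(bad, collapse = ", ")),
                 class = "histotile_value_error")
  }
  as.character(x)
}

#' Classify a tile probability
#'
#' A tile is called immature iff its predicted probability of immature
#' stroma reaches the cutoff; the boundary is inclusive, so 0.5 is
#' immature at the default cutoff.
#'
#' @param prob Probabilities in `[0, 1]` (vectorised).
#' @param cutoff Decision cutoff in `[0, 1]` (default 0.5).
#' @return Character vector of `"mature"` / `"immature"`.
#' @examples
#' classify_tile(c(0.49, 0.5, 1))
#' @export
classify_tile <- function(prob, cutoff = 0.5) {
  if (any(is.na(prob)) || any(prob < 0 | prob > 1)) {
    rlang::abort("Probabilities must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  if (cutoff < 0 || cutoff > 1) {
    rlang::abort("`cutoff` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  ifelse(prob >= cutoff, "immature", "mature")
}

majority_vote <- function(labels, tie) {
  labels <- check_labels(labels, "labels")
  if (length(labels) == 0) {
    rlang::abort("Cannot vote over an empty label set.",
                 class = "histotile_value_error")
  }
  n_imm <- sum(labels == "immature")
  n_mat <- length(labels) - n_imm
  if (n_imm > n_mat) "immature"
  else if (n_mat > n_imm) "mature"
  else tie
}

#' Majority vote of tile labels within an ROI
#'
#' @param tile_labels Character vector of `"mature"` / `"immature"`.
#' @param tie Label returned on an exact tie; `"mature"` by default (the
#'   conservative direction, mirroring the patient-level rule).
#' @return A single label.
#' @export
roi_vote <- function(tile_labels, tie = c("mature", "immature")) {
  majority_vote(tile_labels, match.arg(tie))
}

#' Majority vote of ROI labels for a patient
#'
#' When a patient's ROIs split evenly between mature and immature, the
#' patient is called mature overall.
#'
#' @param roi_labels Character vector of per-ROI labels.
#' @inheritParams roi_vote
#' @return A single label.
#' @examples
#' patient_vote(c("immature", "immature", "mature", "mature"))  # tie -> mature
#' @export
patient_vote <- function(roi_labels, tie = c("mature", "immature")) {
  majority_vote(roi_labels, match.arg(tie))
}

#' Confusion matrix with immature as the positive class
#'
#' Counts follow the convention: true mature = TN, false immature = FP,
#' true immature = TP, false mature = FN.
#'
#' @param true_labels,pred_labels Equal-length label vectors
#'   (`"mature"` / `"immature"`).
#' @return A `confusion_matrix` object (named list `tn`, `fp`, `tp`, `fn`);
#'   build one directly from counts with [confusion_matrix()].
#' @export
confusion <- function(true_labels, pred_labels) {
  true_labels <- check_labels(true_labels, "true_labels")
  pred_labels <- check_labels(pred_labels, "pred_labels")
  if (length(true_labels) != length(pred_labels) || length(true_labels) == 0) {
    rlang::abort("Label vectors must have equal, nonzero length.",
                 class = "histotile_value_error")
  }
  confusion_matrix(
    tn = sum(true_labels == "mature" & pred_labels == "mature"),
    fp = sum(true_labels == "mature" & pred_labels == "immature"),
    tp = sum(true_labels == "immature" & pred_labels == "immature"),
    fn = sum(true_labels == "immature" & pred_labels == "mature"))
}

#' @rdname confusion
#' @param tn,fp,tp,fn Non-negative counts.
#' @export
confusion_matrix <- function(tn, fp, tp, fn) {
  counts <- c(tn = tn, fp = fp, tp = tp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("Confusion counts must be non-negative integers.",
                 class = "histotile_value_error")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(true = stroma_levels, pred = stroma_levels))
  cat("<confusion_matrix> positive class: immature\n")
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix metrics
#'
#' Precision `tp/(tp+fp)`, recall (= sensitivity) `tp/(tp+fn)`, F1 (their
#' harmonic mean), accuracy `(tp+tn)/total` and specificity `tn/(tn+fp)`.
#' Degenerate denominators yield `NA` (undefined), never 0.
#'
#' @param cm A `confusion_matrix`.
#' @return A single numeric value (or `NA` when undefined).
#' @name cm_metrics
#' @examples
#' cm <- confusion_matrix(tn = 764, fp = 275, tp = 1532, fn = 396)
#' round(c(precision(cm), recall(cm), f1(cm), accuracy(cm)), 3)
NULL

#' @rdname cm_metrics
#' @export
precision <- function(cm) safe_ratio(cm$tp, cm$tp + cm$fp)

#' @rdname cm_metrics
#' @export
recall <- function(cm) safe_ratio(cm$tp, cm$tp + cm$fn)

#' @rdname cm_metrics
#' @export
f1 <- function(cm) {
  p <- precision(cm); r <- recall(cm)
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' @rdname cm_metrics
#' @export
accuracy <- function(cm) {
  safe_ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
}

#' @rdname cm_metrics
#' @export
specificity <- function(cm) safe_ratio(cm$tn, cm$tn + cm$fp)

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    metric = c("precision", "recall", "f1", "accuracy", "specificity"),
    value = c(precision(x), recall(x), f1(x), accuracy(x), specificity(x)))
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(tn = x$tn, fp = x$fp, tp = x$tp, fn = x$fn,
                 total = x$tn + x$fp + x$tp + x$fn,
                 accuracy = accuracy(x), precision = precision(x),
                 recall = recall(x), f1 = f1(x),
                 specificity = specificity(x))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from the beta quantiles:
#' lower `qbeta(a/2, x, n - x + 1)` (0 when `x = 0`), upper
#' `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`). Used for sensitivity,
#' specificity and accuracy of patient-level calls, where `n` is small and
#' normal approximations misbehave.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `low`, `high`, `level`.
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    rlang::abort("Need 0 <= successes <= trials, trials >= 1.",
                 class = "histotile_value_error")
  }
  a <- 1 - level
  low <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  tibble::tibble(estimate = successes / trials, low = low, high = high,
                 level = level)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney form: the probability a random immature case receives
#' a higher probability than a random mature case, with midranks giving
#' ties half weight. Invariant under any strictly monotone transform of
#' the probabilities.
#'
#' @param true_labels Labels (`"mature"` / `"immature"`); both classes
#'   must be present.
#' @param probs Predicted probabilities of immature, same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(true_labels, probs) {
  true_labels <- check_labels(true_labels, "true_labels")
  if (length(true_labels) != length(probs)) {
    rlang::abort("Lengths differ.", class = "histotile_value_error")
  }
  pos <- true_labels == "immature"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUC needs both classes present.",
                 class = "histotile_value_error")
  }
  r <- rank(probs)  # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement `(Pbar - Pe) / (1 - Pe)` for `n` items each
#' rated by the same number of raters into categorical classes. Used to
#' quantify concordance between independent assessors (a model counts as
#' one more rater).
#'
#' @param ratings Matrix or data frame, items x raters, of categorical
#'   labels (any common set of values).
#' @return Kappa, or `NA` when expected agreement is 1 (a single category
#'   used throughout).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2 || ncol(ratings) < 2 || anyNA(ratings)) {
    rlang::abort("Need >= 2 items, >= 2 raters, no missing cells.",
                 class = "histotile_value_error")
  }
  cats <- sort(unique(as.vector(ratings)))
  n <- ncol(ratings)  # raters per item
  per_item <- vapply(seq_len(nrow(ratings)), function(i) {
    as.numeric(tabulate(match(ratings[i, ], cats), nbins = length(cats)))
  }, numeric(length(cats)))
  counts <- if (is.matrix(per_item)) t(per_item) else matrix(per_item, ncol = 1)
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_bar - p_e) / (1 - p_e)
}

#' Read a per-tile prediction table
#'
#' @param path CSV with header
#'   `patient_id,roi_id,tile_id,true_label,prob_immature`.
#' @return A validated prediction tibble.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        roi_id = "character",
                                        tile_id = "character"))
  validate_predictions(tibble::as_tibble(tab))
}

validate_predictions <- function(table) {
  needed <- c("patient_id", "roi_id", "tile_id", "true_label", "prob_immature")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    rlang::abort(paste0("Prediction table lacks columns: ",
                        paste(missing, collapse = ", ")),
                 class = "histotile_value_error")
  }
  if (nrow(table) == 0) {
    rlang::abort("Prediction table is empty.",
                 class = "histotile_value_error")
  }
  check_labels(table$true_label, "true_label")
  if (any(table$prob_immature < 0 | table$prob_immature > 1)) {
    rlang::abort("`prob_immature` must lie in [0, 1].",
                 class = "histotile_value_error")
  }
  if (anyDuplicated(table[c("patient_id", "roi_id", "tile_id")])) {
    rlang::abort("(patient, roi, tile) triples must be unique.",
                 class = "histotile_value_error")
  }
  table
}

#' Aggregate tile predictions to ROI and patient level
#'
#' Tiles are classified at the cutoff; ROI labels are the majority vote of
#' their tiles and patient labels the majority vote of their ROIs, exact
#' ties resolving to mature. Ground truth above tile level is derived by
#' the same voting from the tile truth — heterogeneous ROIs/patients are
#' permitted and voted, not rejected. Returns labelled tables and a
#' confusion matrix per level.
#'
#' @param table Prediction tibble with columns `patient_id`, `roi_id`,
#'   `tile_id`, `true_label`, `prob_immature` (see [read_predictions()]).
#' @param cutoff Tile decision cutoff (default 0.5).
#' @param tie Tie-break label for both voting levels (default `"mature"`).
#' @return An `aggregation` object: list with tibbles `tile`, `roi`,
#'   `patient` and `confusion = list(tile =, roi =, patient =)`. `tidy()`
#'   gives a long metric table, `glance()` one row per level.
#' @export
aggregate_predictions <- function(table, cutoff = 0.5,
                                  tie = c("mature", "immature")) {
  tie <- match.arg(tie)
  table <- validate_predictions(tibble::as_tibble(table))
  tile <- dplyr::mutate(table,
                        pred_label = classify_tile(.data$prob_immature, cutoff))
  roi <- tile |>
    dplyr::group_by(.data$patient_id, .data$roi_id) |>
    dplyr::summarise(
      true_label = roi_vote(.data$true_label, tie = tie),
      pred_label = roi_vote(.data$pred_label, tie = tie),
      n_tiles = dplyr::n(), .groups = "drop")
  patient <- roi |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      true_label = patient_vote(.data$true_label, tie = tie),
      pred_label = patient_vote(.data$pred_label, tie = tie),
      n_rois = dplyr::n(), .groups = "drop")
  structure(list(
    tile = tile, roi = roi, patient = patient,
    confusion = list(
      tile = confusion(tile$true_label, tile$pred_label),
      roi = confusion(roi$true_label, roi$pred_label),
      patient = confusion(patient$true_label, patient$pred_label)),
    cutoff = cutoff, tie = tie),
    class = "aggregation")
}

#' @export
print.aggregation <- function(x, ...) {
  cat(sprintf("<aggregation> %d tiles -> %d ROIs -> %d patients (cutoff %.2f, ties -> %s)\n",
              nrow(x$tile), nrow(x$roi), nrow(x$patient), x$cutoff, x$tie))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.aggregation <- function(x, ...) {
  purrr::map_dfr(c("tile", "roi", "patient"), function(level) {
    dplyr::mutate(tidy(x$confusion[[level]]), level = level, .before = 1)
  })
}

#' @export
glance.aggregation <- function(x, ...) {
  purrr::map_dfr(c("tile", "roi", "patient"), function(level) {
    dplyr::mutate(glance(x$confusion[[level]]), level = level, .before = 1)
  })
}

#' ROC curve for an aggregation's tile probabilities
#'
#' @param object An `aggregation` from [aggregate_predictions()].
#' @param ... Unused.
#' @return A ggplot of the tile-level ROC curve, AUC in the subtitle.
#' @export
autoplot.aggregation <- function(object, ...) {
  tile <- object$tile
  thr <- c(Inf, sort(unique(tile$prob_immature), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- ifelse(tile$prob_immature >= t, "immature", "mature")
    cm <- confusion(tile$true_label, pred)
    tibble::tibble(fpr = 1 - specificity(cm), tpr = recall(cm))
  })
  auc <- roc_auc(tile$true_label, tile$prob_immature)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Tile-level ROC",
                  subtitle = sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}
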