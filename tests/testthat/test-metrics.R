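test_that("tile classification is inclusive at the cutoff", {
  expect_identical(classify_tile(c(0.49, 0.5, 0, 1)),
                   c("mature", "immature", "mature", "immature"))
  expect_error(classify_tile(1.2), class = "histotile_value_error")
  expect_error(classify_tile(0.5, cutoff = -0.1),
               class = "histotile_value_error")
})

test_that("ROI and patient votes take majorities with ties to mature", {
  expect_identical(roi_vote(c("immature", "immature", "mature")), "immature")
  expect_identical(roi_vote(c("mature", "immature")), "mature")
  expect_identical(roi_vote("immature"), "immature")
  expect_identical(patient_vote(rep(c("immature", "mature"), each = 2)),
                   "mature")
  expect_identical(patient_vote(c(rep("immature", 3), "mature")), "immature")
  expect_identical(patient_vote("mature"), "mature")
  expect_identical(roi_vote(c("mature", "immature"), tie = "immature"),
                   "immature")
  expect_error(roi_vote(character(0)), class = "histotile_value_error")
})

test_that("flipping one tile toward immature never moves a vote toward mature", {
  withr::with_seed(91, {
    for (rep in 1:25) {
      n <- sample(1:9, 1)
      labs <- sample(c("mature", "immature"), n, replace = TRUE)
      before <- roi_vote(labs)
      i <- which(labs == "mature")
      if (length(i) == 0) next
      labs[i[1]] <- "immature"
      after <- roi_vote(labs)
      expect_false(before == "immature" && after == "mature")
    }
  })
})

test_that("confusion counts follow the immature-positive convention", {
  t5 <- rep(c("mature", "immature"), each = 5)
  perfect <- confusion(t5, t5)
  expect_equal(unlist(perfect[c("tn", "fp", "tp", "fn")]),
               c(tn = 5L, fp = 0L, tp = 5L, fn = 0L))
  all_imm <- confusion(t5, rep("immature", 10))
  expect_equal(unlist(all_imm[c("tn", "fp", "tp", "fn")]),
               c(tn = 0L, fp = 5L, tp = 5L, fn = 0L))
  withr::with_seed(17, {
    tl <- sample(c("mature", "immature"), 60, replace = TRUE)
    pl <- sample(c("mature", "immature"), 60, replace = TRUE)
  })
  cm <- confusion(tl, pl)
  expect_equal(cm$tp, sum(tl == "immature" & pl == "immature"))
  expect_equal(cm$fn, sum(tl == "immature" & pl == "mature"))
  expect_equal(cm$tn + cm$fp + cm$tp + cm$fn, 60)
  expect_error(confusion(tl, pl[-1]), class = "histotile_value_error")
  expect_error(confusion("yes", "no"), class = "histotile_value_error")
})

test_that("metric identities hold and degenerate denominators give NA", {
  cm <- confusion_matrix(tn = 13, fp = 2, tp = 11, fn = 2)
  expect_equal(accuracy(cm), 24 / 28)
  expect_equal(specificity(cm), 13 / 15)
  p <- precision(cm); r <- recall(cm)
  expect_equal(f1(cm), 2 * p * r / (p + r))
  z <- confusion_matrix(tn = 5, fp = 0, tp = 0, fn = 0)
  expect_true(is.na(precision(z)))
  expect_true(is.na(recall(z)))
  expect_equal(specificity(z), 1)
  expect_equal(specificity(confusion_matrix(0, 5, 5, 0)), 0)
  td <- tidy(cm)
  expect_equal(td$value[td$metric == "accuracy"], 24 / 28)
  expect_equal(glance(cm)$total, 28)
})

test_that("exact binomial intervals match the beta-quantile oracle and bounds", {
  expect_equal(exact_binomial_ci(15, 15)$high, 1)
  expect_equal(exact_binomial_ci(0, 15)$low, 0)
  ci <- exact_binomial_ci(12, 15)
  bt <- stats::binom.test(12, 15)$conf.int
  expect_equal(ci$low, bt[1], tolerance = 1e-10)
  expect_equal(ci$high, bt[2], tolerance = 1e-10)
  expect_error(exact_binomial_ci(5, 4), class = "histotile_value_error")
})

test_that("rank AUC equals the pairwise oracle, including ties", {
  truth <- c("mature", "mature", "mature", "immature", "immature", "immature")
  sep <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  expect_equal(roc_auc(truth, sep), 1)
  expect_equal(roc_auc(truth, rep(0.5, 6)), 0.5)
  toy <- c(0.2, 0.5, 0.5, 0.5, 0.7, 0.9)
  expect_equal(roc_auc(truth, toy), auc_oracle(truth, toy))
  withr::with_seed(29, {
    for (rep in 1:20) {
      n <- sample(6:20, 1)
      tl <- c("mature", "immature",
              sample(c("mature", "immature"), n - 2, replace = TRUE))
      pr <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forced ties
      expect_equal(roc_auc(tl, pr), auc_oracle(tl, pr), tolerance = 1e-12)
      # invariance under strictly monotone transform
      expect_equal(roc_auc(tl, pr), roc_auc(tl, plogis(5 * pr - 2)),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(rep("mature", 4), runif(4)),
               class = "histotile_value_error")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(37, {
    tl <- sample(c("mature", "immature"), 50, replace = TRUE)
    tl[1:2] <- c("mature", "immature")
    pr <- round(runif(50), 2)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(tl, levels = c("mature", "immature")),
    predictor = pr, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(tl, pr), ref, tolerance = 1e-12)
})

test_that("Fleiss' kappa matches a hand-worked table and behaves at the limits", {
  # 4 items, 3 raters
  ratings <- rbind(c("a", "a", "a"),
                   c("a", "a", "b"),
                   c("b", "b", "b"),
                   c("a", "b", "b"))
  # hand computation: P_i = (sum n_ij^2 - n) / (n(n-1))
  # counts: (3,0),(2,1),(0,3),(1,2) -> P_i = 1, 1/3, 1, 1/3; Pbar = 2/3
  # p_a = 6/12, p_b = 6/12 -> Pe = 1/2; kappa = (2/3 - 1/2)/(1/2) = 1/3
  expect_equal(fleiss_kappa(ratings), 1 / 3)
  agree <- rbind(c("a", "a"), c("b", "b"), c("a", "a"))
  expect_equal(fleiss_kappa(agree), 1)
  single <- rbind(c("a", "a"), c("a", "a"))
  expect_true(is.na(fleiss_kappa(single)))
  withr::with_seed(43, {
    null_tab <- matrix(sample(c("x", "y"), 600 * 4, replace = TRUE), 600, 4)
  })
  expect_lt(abs(fleiss_kappa(null_tab)), 0.05)
  expect_error(fleiss_kappa(rbind(c("a", "b"))),
               class = "histotile_value_error")
})

test_that("aggregation votes tiles into ROIs and patients with the tie rule", {
  tab <- tibble::tibble(
    patient_id = "pt1",
    roi_id = rep(c("r1", "r2"), each = 3),
    tile_id = paste0("t", 1:6),
    true_label = rep(c("immature", "mature"), each = 3),
    prob_immature = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3))
  agg <- aggregate_predictions(tab)
  expect_identical(agg$roi$pred_label, c("immature", "mature"))
  expect_identical(agg$patient$pred_label, "mature")  # 1-1 ROI tie -> mature
  expect_identical(agg$patient$true_label, "mature")
  # all-confident case: perfect at every level
  tab2 <- dplyr::mutate(tab, true_label = "immature",
                        prob_immature = 0.9)
  agg2 <- aggregate_predictions(tab2)
  for (level in c("tile", "roi", "patient")) {
    cm <- agg2$confusion[[level]]
    expect_equal(cm$fp + cm$fn, 0)
  }
})

test_that("aggregation matrices equal a direct enumeration oracle", {
  withr::with_seed(53, {
    rows <- list()
    for (p in 1:5) for (r in 1:sample(2:3, 1)) {
      n <- sample(3:5, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = paste0("p", p), roi_id = paste0("r", r),
        tile_id = paste0("t", seq_len(n)),
        true_label = sample(c("mature", "immature"), n, replace = TRUE),
        prob_immature = round(runif(n), 2))
    }
    tab <- dplyr::bind_rows(rows)
  })
  agg <- aggregate_predictions(tab, cutoff = 0.5)
  # oracle: explicit loops, no dplyr
  vote <- function(x) {
    ni <- sum(x == "immature"); nm <- sum(x == "mature")
    if (ni > nm) "immature" else "mature"
  }
  tl <- ifelse(tab$prob_immature >= 0.5, "immature", "mature")
  expect_identical(agg$tile$pred_label, tl)
  key <- paste(tab$patient_id, tab$roi_id)
  roi_true <- roi_pred <- character(0)
  for (k in unique(key)) {
    roi_true <- c(roi_true, vote(tab$true_label[key == k]))
    roi_pred <- c(roi_pred, vote(tl[key == k]))
  }
  cm_roi <- agg$confusion$roi
  expect_equal(cm_roi$tp, sum(roi_true == "immature" & roi_pred == "immature"))
  expect_equal(cm_roi$tn, sum(roi_true == "mature" & roi_pred == "mature"))
  pk <- sub(" .*", "", unique(key))
  pat_true <- pat_pred <- character(0)
  for (p in unique(pk)) {
    pat_true <- c(pat_true, vote(roi_true[pk == p]))
    pat_pred <- c(pat_pred, vote(roi_pred[pk == p]))
  }
  cm_p <- agg$confusion$patient
  expect_equal(cm_p$tp, sum(pat_true == "immature" & pat_pred == "immature"))
  expect_equal(cm_p$fn, sum(pat_true == "immature" & pat_pred == "mature"))
  g <- glance(agg)
  expect_equal(g$level, c("tile", "roi", "patient"))
  expect_equal(g$total[1], nrow(tab))
})

test_that("prediction tables validate probabilities and uniqueness", {
  tab <- tibble::tibble(patient_id = "p", roi_id = "r", tile_id = c("t", "t"),
                        true_label = "mature", prob_immature = 0.5)
  expect_error(aggregate_predictions(tab), class = "histotile_value_error")
  tab2 <- tibble::tibble(patient_id = "p", roi_id = "r", tile_id = "t",
                         true_label = "mature", prob_immature = 1.5)
  expect_error(aggregate_predictions(tab2), class = "histotile_value_error")
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  good <- tibble::tibble(patient_id = "p1", roi_id = "r1",
                         tile_id = c("t1", "t2"),
                         true_label = c("mature", "immature"),
                         prob_immature = c(0.2, 0.8))
  utils::write.csv(good, f, row.names = FALSE)
  expect_equal(read_predictions(f), good)
})
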