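test_that("confusion counts use the strictly-greater decision rule", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # a score exactly at the threshold is a negative call
  cc2 <- confusion(c(1), c(0.5))
  expect_identical(cc2$FN, 1L)
  expect_identical(cc2$TP, 0L)
  n <- 25L
  cc3 <- confusion(rep(1, n), rep(1.0, n))
  expect_identical(cc3$TP, n)
  expect_error(confusion(c(1, 0), c(0.5)), "equal length")
})

test_that("five metrics agree with definitional formulas on random tables", {
  set.seed(701)
  for (trial in 1:200) {
    counts <- as.list(stats::setNames(sample(0:80, 4, replace = TRUE),
                                      c("TP", "TN", "FP", "FN")))
    if (sum(unlist(counts)) == 0) next
    got <- suppressWarnings(metrics_from_counts(do.call(confusion_counts,
                                                        counts)))
    want <- oracle_metrics(counts$TP, counts$TN, counts$FP, counts$FN)
    for (mn in names(want)) {
      expect_equal(got[[mn]], want[[mn]], tolerance = 1e-12,
                   label = sprintf("%s for %s", mn,
                                   paste(unlist(counts), collapse = "/")))
    }
  }
})

test_that("sum rule and perfect-classifier behavior hold", {
  cc <- confusion(rep(c(1, 0), 10), rep(c(0.9, 0.1), 10))
  expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 20L)
  perfect <- metrics_from_counts(confusion_counts(10, 10, 0, 0))
  expect_identical(
    unlist(perfect[c("sensitivity", "specificity", "f1", "accuracy")]),
    c(sensitivity = 1, specificity = 1, f1 = 1, accuracy = 1))
  expect_identical(perfect$mcc, 1)
})

test_that("degenerate denominators report 0 with a warning", {
  expect_warning(rep_ <- metrics_from_counts(confusion_counts(0, 5, 0, 0)),
                 "zero denominator")
  expect_identical(rep_$sensitivity, 0)
  expect_identical(rep_$mcc, 0)
})

test_that("ROC endpoints, symmetry and the Mann-Whitney identity hold", {
  lab <- c(1, 1, 0, 0)
  perfect <- roc_auc(lab, c(0.9, 0.8, 0.2, 0.1))
  expect_identical(perfect$auc, 1)
  expect_true(all(diff(perfect$fpr) >= 0))
  expect_true(all(diff(perfect$tpr) >= 0))
  expect_identical(perfect$fpr[1], 0)
  expect_identical(perfect$tpr[length(perfect$tpr)], 1)

  set.seed(702)
  for (trial in 1:50) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), 2)  # rounding forces ties
    r <- roc_auc(labels, scores)
    expect_equal(r$auc, oracle_auc_mw(labels, scores), tolerance = 1e-12)
    flipped <- roc_auc(1 - labels, scores)
    expect_equal(flipped$auc, 1 - r$auc, tolerance = 1e-12)
    # invariant to strictly monotone transformation of scores
    expect_equal(roc_auc(labels, stats::qlogis(pmin(pmax(scores, 1e-3),
                                                    1 - 1e-3)))$auc,
                 roc_auc(labels, pmin(pmax(scores, 1e-3), 1 - 1e-3))$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), stats::runif(5)), "both classes")
})

test_that("AUC matches pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(703)
  for (trial in 1:10) {
    labels <- c(0, 1, sample(0:1, 200, replace = TRUE))
    scores <- stats::runif(202)
    expect_equal(roc_auc(labels, scores)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("label-shuffled scores give chance-level AUC", {
  set.seed(704)
  labels <- sample(rep(0:1, 500))
  scores <- stats::runif(1000)
  expect_true(abs(roc_auc(labels, scores)$auc - 0.5) < 0.05)
})

test_that("cross-validation wiring: k reports, SE formula, stratification", {
  # plumbing check on an easily separable toy problem, tiny epochs
  set.seed(705)
  seqs <- character(90)
  labels <- rep_len(c(1L, 0L), 90)
  for (i in 1:90) {
    base <- if (labels[i] == 1L) c("A", "G") else c("U", "C")
    seqs[i] <- paste(sample(base, 110, TRUE), collapse = "")
  }
  tab <- data.frame(chimera_seq = seqs, label = labels,
                    stringsAsFactors = FALSE)
  cv <- cross_validate(tab, k = 3, config = training_config(
    max_epochs = 4L, batch_size = 16L, early_stop_patience = 4L,
    seed = 11L))
  expect_identical(nrow(cv$per_fold), 3L)
  expect_identical(cv$k, 3L)
  for (mn in names(cv$mean)) {
    expect_equal(cv$mean[[mn]], mean(cv$per_fold[[mn]]), tolerance = 1e-12)
    expect_equal(cv$se[[mn]], stats::sd(cv$per_fold[[mn]]) / sqrt(3),
                 tolerance = 1e-12)
  }
  # single-class folds are rejected up front
  one_class <- tab
  one_class$label <- 1L
  one_class$label[1] <- 0L
  expect_error(cross_validate(one_class, k = 3,
                              config = training_config(seed = 1L)),
               "single class")
})
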