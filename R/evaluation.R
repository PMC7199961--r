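#' Confusion counts at a decision threshold
#'
#' A score counts as a positive prediction when it is strictly greater
#' than the threshold (default 0.5).
#'
#' @param labels 0/1 vector of true classes.
#' @param scores numeric vector of predicted probabilities, same length.
#' @param threshold decision threshold; default 0.5.
#' @return a list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  stopifnot(all(labels %in% 0:1))
  pred <- scores > threshold
  structure(list(TP = sum(pred & labels == 1L),
                 TN = sum(!pred & labels == 0L),
                 FP = sum(pred & labels == 0L),
                 FN = sum(!pred & labels == 1L)),
            class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")
}

#' The five classification metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), F1-score
#' 2TP/(2TP+FP+FN), the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TN+FN)(TP+FP)), and accuracy
#' (TP+TN)/n. Any metric whose denominator is zero is reported as 0 with
#' the `degenerate` flag set (a reporting convention, not a statement that
#' the classifier is uninformative).
#'
#' @param c a `confusion_counts` object (or list with TP, TN, FP, FN).
#' @return a list of class `metrics_report` with `sensitivity`,
#'   `specificity`, `f1`, `mcc`, `accuracy` (fractions; MCC in [-1, 1]),
#'   plus `counts` and `degenerate`.
#' @export
metrics_from_counts <- function(c) {
  TP <- as.numeric(c$TP); TN <- as.numeric(c$TN)
  FP <- as.numeric(c$FP); FN <- as.numeric(c$FN)
  n <- TP + TN + FP + FN
  degenerate <- character()
  safe_div <- function(num, den, name) {
    if (den <= 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  sen <- safe_div(TP, TP + FN, "sensitivity")
  spe <- safe_div(TN, TN + FP, "specificity")
  f1 <- safe_div(2 * TP, 2 * TP + FP + FN, "f1")
  mcc_den <- (TP + FN) * (TN + FP) * (TN + FN) * (TP + FP)
  mcc <- if (mcc_den <= 0) { degenerate <- c(degenerate, "mcc"); 0 } else {
    (TP * TN - FP * FN) / sqrt(mcc_den)
  }
  acc <- safe_div(TP + TN, n, "accuracy")
  if (length(degenerate)) {
    warning("zero denominator; reported as 0 for: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  structure(list(sensitivity = sen, specificity = spe, f1 = f1, mcc = mcc,
                 accuracy = acc,
                 counts = list(TP = TP, TN = TN, FP = FP, FN = FN),
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Sen. %.2f%%  Spe. %.2f%%  F1 %.2f%%  MCC %.2f%%  Acc. %.2f%%\n",
    100 * x$sensitivity, 100 * x$specificity, 100 * x$f1, 100 * x$mcc,
    100 * x$accuracy))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold from above the largest score downwards,
#' recording the false and true positive rates; the AUC is the trapezoidal
#' area under the resulting curve (invariant to strictly monotone
#' transformations of the scores).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, same length.
#' @return a list of class `roc_curve` with `thresholds` (descending,
#'   starting at `Inf`), `fpr`, `tpr` (non-decreasing) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  stopifnot(all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes in `labels`", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single thresholds
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp_cum <- cumsum(l == 1L)[last_of_tie]
  fp_cum <- cumsum(l == 0L)[last_of_tie]
  thresholds <- c(Inf, s[last_of_tie])
  tpr <- c(0, tp_cum / n_pos)
  fpr <- c(0, fp_cum / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' k-fold cross-validation of the CNN
#'
#' Splits the dataset into k folds (stratified by label by default), trains
#' on k-1 folds -- carving a small validation slice out of the training
#' rows for early stopping -- and evaluates the five metrics plus AUC on
#' the held-out fold. The summary reports the per-metric mean and standard
#' error (sample standard deviation divided by sqrt(k)).
#'
#' @param table dataset table with both classes.
#' @param k number of folds, default 10.
#' @param arch a [build_architecture()] spec.
#' @param config a [training_config()]; `config$seed` fixes folds and all
#'   per-fold training.
#' @param stratify stratify folds by label? Default `TRUE`.
#' @param val_fraction fraction of each training split reserved for early
#'   stopping, default 0.1.
#' @param threshold decision threshold for the counts, default 0.5.
#' @param verbose print per-fold progress? Default `FALSE`.
#' @return a list of class `cv_summary` with `per_fold` (`data.frame`, one
#'   row per fold), `mean` and `se` (named numeric vectors), `k`.
#' @export
cross_validate <- function(table, k = 10L, arch = build_architecture(),
                           config = training_config(), stratify = TRUE,
                           val_fraction = 0.1, threshold = 0.5,
                           verbose = FALSE) {
  table <- validate_dataset_table(table)
  k <- as.integer(k)
  folds <- kfold_split(table, k, seed = derive_seed(config$seed, 1L),
                       stratify = stratify)
  bad <- which(vapply(folds, function(f) length(unique(f$label)) < 2L,
                      logical(1)))
  if (length(bad)) {
    stop("fold(s) with a single class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  metric_names <- c("sensitivity", "specificity", "f1", "mcc", "accuracy",
                    "auc")
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_tab <- folds[[f]]
    train_tab <- do.call(rbind, folds[-f])
    n_val <- max(1L, round(val_fraction * nrow(train_tab)))
    parts <- split_dataset(train_tab,
                           c(nrow(train_tab) - n_val, n_val, 0L),
                           seed = derive_seed(config$seed, 100L + f))
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, 200L + f)
    model <- train_cnn(arch, encode_batch(parts$train),
                       encode_batch(parts$validation), fold_config)
    scores <- predict(model, encode_batch(test_tab))
    rep_ <- metrics_from_counts(confusion(test_tab$label, scores,
                                          threshold))
    auc <- roc_auc(test_tab$label, scores)$auc
    rows[[f]] <- data.frame(fold = f, sensitivity = rep_$sensitivity,
                            specificity = rep_$specificity, f1 = rep_$f1,
                            mcc = rep_$mcc, accuracy = rep_$accuracy,
                            auc = auc)
    if (verbose) {
      message(sprintf("fold %2d/%d  acc %.4f  auc %.4f", f, k,
                      rep_$accuracy, auc))
    }
  }
  per_fold <- do.call(rbind, rows)
  mean_v <- vapply(metric_names, function(mn) mean(per_fold[[mn]]),
                   numeric(1))
  se_v <- vapply(metric_names,
                 function(mn) stats::sd(per_fold[[mn]]) / sqrt(k),
                 numeric(1))
  structure(list(per_fold = per_fold, mean = mean_v, se = se_v, k = k),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (mean +/- SE, %%):\n", x$k))
  for (mn in names(x$mean)) {
    cat(sprintf("  %-12s %6.2f +/- %.2f\n", mn, 100 * x$mean[[mn]],
                100 * x$se[[mn]]))
  }
  invisible(x)
}
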