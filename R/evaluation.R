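# Phase-3 evaluation: confusion matrix, its derived metrics (accuracy,
# precision, recall, F1, Matthews correlation coefficient), rank-based AUC,
# and mean +/- sd summaries over repeated experiments.

#' Binary confusion matrix
#'
#' Positive class is 1. Counts: TP (true 1 predicted 1), TN (true 0
#' predicted 0), FP (true 0 predicted 1), FN (true 1 predicted 0).
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return an object of class `confusion_matrix` with integer fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort_deepens("y_true and y_pred must have equal length", "deepens_input_error")
  }
  if (length(y_true) == 0) {
    abort_deepens("cannot build a confusion matrix from empty vectors",
                  "deepens_input_error")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort_deepens("labels and predictions must be 0/1", "deepens_input_error")
  }
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Derive classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators (e.g. no positive predictions, or a zero factor
#' under the MCC root) yield 0 with a warning — the conventional fallback.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metric_report` list with `accuracy`, `precision`, `recall`,
#'   `f1`, `mcc` (and `auc = NA`, fill via [compute_auc()]).
#' @export
derive_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  if (total < 1) abort_deepens("empty confusion matrix", "deepens_input_error")
  accuracy <- (TP + TN) / total
  precision <- if (TP + FP == 0) {
    warning("no positive predictions: precision set to 0"); 0
  } else TP / (TP + FP)
  recall <- if (TP + FN == 0) {
    warning("no positive samples: recall set to 0"); 0
  } else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) {
    warning("degenerate confusion matrix: MCC set to 0"); 0
  } else (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc, auc = NA_real_),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> acc=%.4f prec=%.4f rec=%.4f f1=%.4f mcc=%.4f auc=%s\n",
    x$accuracy, x$precision, x$recall, x$f1, x$mcc,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Area under the ROC curve from scores
#'
#' Computed as the Mann--Whitney rank statistic: the probability that a
#' random positive outscores a random negative, ties counted one half.
#'
#' @param y_true 0/1 vector containing both classes.
#' @param scores real-valued scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    abort_deepens("y_true and scores must have equal length", "deepens_input_error")
  }
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort_deepens("AUC requires both classes present", "deepens_input_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predictions against labels in one call
#'
#' @param y_true 0/1 labels.
#' @param pred a [prediction_vector()] (or a numeric score vector).
#' @param threshold class threshold when `pred` is numeric.
#' @return a `metric_report` including AUC (NA when only one class present).
#' @export
evaluate_predictions <- function(y_true, pred, threshold = 0.5) {
  if (inherits(pred, "prediction_vector")) {
    scores <- pred$scores; classes <- pred$classes
  } else {
    scores <- pred; classes <- as.integer(pred >= threshold)
  }
  rep <- derive_metrics(confusion_matrix(y_true, classes))
  if (length(unique(y_true)) == 2) rep$auc <- compute_auc(y_true, scores)
  rep
}

#' Summarise repeated metric reports as mean and standard deviation
#'
#' Aggregates a list of `metric_report`s into the reporting format used for
#' repeated experiments: per metric, the mean m and the population standard
#' deviation d across repetitions, rendered as `"m +/- d"` with two
#' decimals.
#'
#' @param reports list of at least two `metric_report`s with identical
#'   metric sets.
#' @return a `summary_report`: data.frame with columns `metric`, `mean`,
#'   `sd`, `formatted`; attribute `n_repeats`.
#' @export
summarize_repeats <- function(reports) {
  if (length(reports) < 2) {
    abort_deepens("need >= 2 reports to summarise", "deepens_input_error")
  }
  metrics <- names(reports[[1]])
  for (r in reports) {
    if (!identical(names(r), metrics)) {
      abort_deepens("inconsistent metric sets across reports", "deepens_input_error")
    }
  }
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) as.numeric(r[[m]]), 0)
    mu <- mean(v)
    d <- sqrt(mean((v - mu)^2))          # population sd across repetitions
    data.frame(metric = m, mean = mu, sd = d,
               formatted = format_m_pm_d(mu, d))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_repeats") <- length(reports)
  class(out) <- c("summary_report", "data.frame")
  out
}

#' Format a mean and deviation as `"m +/- d"` with 2-decimal rounding
#' @param m,d mean and standard deviation.
#' @return character scalar, e.g. `"0.87 ± 0.01"`.
#' @export
format_m_pm_d <- function(m, d) {
  if (is.na(m) || is.na(d)) return(NA_character_)
  sprintf("%.2f ± %.2f", round(m, 2), round(d, 2))
}

#' Render a models-by-metrics grid of `"m +/- d"` cells
#'
#' @param summaries named list of `summary_report`s (one per model).
#' @return character vector of report lines (also printed invisibly usable
#'   with `cat`).
#' @export
format_comparison_grid <- function(summaries) {
  metrics <- summaries[[1]]$metric
  header <- paste(c(sprintf("%-28s", "Model"),
                    sprintf("%-14s", metrics)), collapse = "")
  lines <- vapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    cells <- vapply(metrics, function(m) {
      row <- s[s$metric == m, ]
      if (nrow(row) == 0 || is.na(row$formatted)) "-" else row$formatted
    }, "")
    paste(c(sprintf("%-28s", nm), sprintf("%-14s", cells)), collapse = "")
  }, "")
  c(header, lines)
}

#' Export a metric or summary report as CSV / JSON
#' @param report a `metric_report` or `summary_report`.
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      if (inherits(report, "summary_report")) as.data.frame(report)
      else unclass(report),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- if (inherits(report, "summary_report")) as.data.frame(report)
          else data.frame(metric = names(unclass(report)),
                          value = unlist(unclass(report)), row.names = NULL)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
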