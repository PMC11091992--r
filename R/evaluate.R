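# In-sample evaluation of the pattern-to-injury predictor.
#
# For the saturated model the fitted class probabilities given a pattern are
# the observed class frequencies of that pattern's row, so the maximum-
# probability predictor is the row's modal class. Evaluation is in-sample
# (the same observations that built the table), mirroring how such
# contingency-table predictors are reported clinically.

#' Predict the injury class from a curve pattern
#'
#' Returns, for each pattern, the class with the maximal fitted probability
#' under the saturated multinomial model -- the modal class of the pattern's
#' row of the count table. Ties are broken deterministically by the fixed
#' class order `ACL, MS, PFJ, ACL+MS, Healthy`.
#'
#' @param pattern Vector of pattern labels.
#' @param table 4 x 5 pattern-by-class count matrix defining the predictor.
#' @return Factor of predicted injury classes.
#' @export
#' @examples
#' predict_class(c("Normal", "Valley"), reference_pattern_counts())
predict_class <- function(pattern, table = reference_pattern_counts()) {
  table <- .validate_count_table(table)
  modal <- injury_classes()[apply(table, 1L, which.max)]
  names(modal) <- rownames(table)
  .as_class(modal[as.character(.as_pattern(pattern))])
}

.f1 <- function(precision, recall) {
  if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
}

#' Evaluate the pattern-to-injury predictor
#'
#' Applies [predict_class()] to every observation and summarizes the result
#' as a 5 x 5 confusion matrix (rows = actual class, columns = predicted)
#' with per-class recall (sensitivity), precision (positive predictive
#' value) and F1, the macro-averaged F1 (unweighted mean over the five
#' classes) and the overall accuracy. Undefined ratios (empty row or column,
#' or precision + recall = 0) score 0; a class with neither actual nor
#' predicted observations is not part of the task and is left out of the
#' macro average.
#'
#' @param labels Data frame with columns `pattern` and `class`, one row per
#'   observation.
#' @param table Count table defining the predictor; defaults to the table
#'   built from `labels` itself (in-sample evaluation).
#' @return Object of class `imc_evaluation`: list with `confusion` (matrix),
#'   `per_class` (data frame `class`, `recall`, `precision`, `f1`),
#'   `macro_f1`, `accuracy` and `n`.
#' @export
#' @examples
#' ev <- evaluate_predictions(counts_to_labels())
#' ev$accuracy  # 0.561
evaluate_predictions <- function(labels, table = NULL) {
  if (nrow(labels) == 0L) stop("no observations to evaluate")
  if (is.null(table)) table <- build_contingency(labels)
  actual <- .as_class(labels$class)
  predicted <- predict_class(labels$pattern, table)
  confusion <- matrix(
    as.integer(table(actual, predicted)), nrow = 5L,
    dimnames = list(actual = injury_classes(), predicted = injury_classes())
  )
  per_class <- do.call(rbind, lapply(injury_classes(), function(k) {
    tp <- confusion[k, k]
    row_sum <- sum(confusion[k, ])
    col_sum <- sum(confusion[, k])
    recall <- if (row_sum > 0) tp / row_sum else 0
    precision <- if (col_sum > 0) tp / col_sum else 0
    data.frame(class = k, recall = recall, precision = precision,
               f1 = .f1(precision, recall))
  }))
  in_task <- rowSums(confusion) + colSums(confusion) > 0
  structure(
    list(confusion = confusion, per_class = per_class,
         macro_f1 = mean(per_class$f1[in_task]),
         accuracy = sum(diag(confusion)) / sum(confusion),
         n = sum(confusion)),
    class = "imc_evaluation"
  )
}

#' @export
print.imc_evaluation <- function(x, ...) {
  cat(sprintf("Pattern-to-injury predictor, in-sample over %d observations\n",
              x$n))
  print(x$confusion)
  df <- x$per_class
  df[-1L] <- lapply(df[-1L], round, 3)
  print(df, row.names = FALSE)
  cat(sprintf("Macro-averaged F1: %.3f   Accuracy: %.1f%%\n",
              x$macro_f1, 100 * x$accuracy))
  invisible(x)
}
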