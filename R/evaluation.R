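#' Confusion matrix for four-state classification
#'
#' Rows are true classes, columns predicted, both in canonical order.
#'
#' @param true,predicted character vectors of class labels.
#' @return Object of class `mi_confusion` with `counts`,
#'   `per_class_accuracy` and `overall_accuracy`.
#' @export
confusion_matrix <- function(true, predicted) {
  lv <- class_levels()
  counts <- table(true = factor(true, levels = lv),
                  predicted = factor(predicted, levels = lv))
  counts <- unclass(counts)
  row_tot <- rowSums(counts)
  per_class <- ifelse(row_tot > 0, diag(counts) / row_tot, NA_real_)
  structure(list(counts = counts,
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(counts)) / sum(counts)),
            class = "mi_confusion")
}

#' @export
print.mi_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$counts)
  cat("Per-class accuracy:",
      paste(sprintf("%s %.0f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' Evaluate a fitted classifier on held-out features
#'
#' @param model a `knnsvm_model`.
#' @param features feature matrix of the test trials.
#' @param labels true labels of the test trials.
#' @param predictor prediction function `(model, features) -> labels`;
#'   defaults to the hybrid classifier.
#' @return An [confusion_matrix()] result.
#' @export
evaluate_features <- function(model, features, labels,
                              predictor = function(m, x) predict(m, x)) {
  if (length(labels) == 0) stop("empty test set")
  confusion_matrix(labels, predictor(model, features))
}

#' Compare classifiers on identical features and splits
#'
#' Fits and evaluates each classifier of the roster on the same
#' per-subject train/test feature splits and tabulates per-subject
#' accuracies, the mean, and the across-subject standard deviation
#' (n - 1 denominator).
#'
#' Available roster entries: `knn` (four-class cosine KNN vote), `svm`
#' (one-against-one SVM vote), `knnsvm` (hybrid), `lda` (linear
#' discriminant analysis) and `nb` (naive Bayes).
#'
#' @param splits list with one element per subject, each a list with
#'   `train_x`, `train_y`, `test_x`, `test_y`.
#' @param roster character vector of classifier names.
#' @param k,kernel,cost passed to [knnsvm_fit()].
#' @return data.frame with one row per classifier: per-subject
#'   accuracies, `mean` and `sd`.
#' @export
compare_classifiers <- function(splits,
                                roster = c("knn", "svm", "knnsvm"),
                                k = 5, kernel = "radial", cost = 1) {
  if (length(roster) == 0) stop("empty roster")
  acc_one <- function(name, sp) {
    if (name %in% c("knn", "svm", "knnsvm")) {
      model <- knnsvm_fit(sp$train_x, sp$train_y, k = k, kernel = kernel,
                          cost = cost)
      pred <- switch(name,
                     knn = predict_knn(model, sp$test_x),
                     svm = predict_svm(model, sp$test_x),
                     knnsvm = predict(model, sp$test_x))
    } else if (name == "lda") {
      fit <- MASS::lda(sp$train_x,
                       factor(sp$train_y, levels = class_levels()))
      pred <- as.character(stats::predict(fit, sp$test_x)$class)
    } else if (name == "nb") {
      fit <- e1071::naiveBayes(sp$train_x,
                               factor(sp$train_y, levels = class_levels()))
      pred <- as.character(stats::predict(fit, sp$test_x))
    } else stop("unknown classifier: ", name)
    mean(pred == sp$test_y)
  }
  rows <- lapply(roster, function(name) {
    acc <- vapply(splits, function(sp) acc_one(name, sp), numeric(1))
    data.frame(classifier = name,
               t(stats::setNames(100 * acc,
                                 paste0("subject_", seq_along(acc)))),
               mean = 100 * mean(acc),
               sd = if (length(acc) > 1) stats::sd(100 * acc) else NA_real_)
  })
  do.call(rbind, rows)
}
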