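#' Grid search over the two regularization parameters
#'
#' Evaluates every `(beta, gamma)` combination on a regular grid (step
#' 0.1 gives the full 11 x 11 = 121 cells) and returns the accuracy
#' matrix and the best cell. The per-class covariance summaries and
#' per-trial feature covariances are computed once and reused across
#' cells.
#'
#' Two selection protocols are available. The default scores each cell by
#' stratified cross-validation within the subject's own training split,
#' which keeps the test set untouched during model selection. The
#' "holdout" mode scores each cell directly on a supplied test split.
#'
#' @param own the subject's [eeg_dataset()] (preprocessed trials).
#' @param generic list of the other subjects' datasets.
#' @param grid_step grid spacing in `[0, 1]` (default 0.1).
#' @param alpha filters kept per spectrum end (see [rcsp_config()]).
#' @param mode "cv" (default) or "holdout".
#' @param folds number of cross-validation folds (cv mode).
#' @param k,kernel,cost classifier hyperparameters (see [knnsvm_fit()]).
#' @param seed seed for the fold assignment (cv mode).
#' @return List with `best` (an [rcsp_config()]), `accuracy` (matrix with
#'   beta rows, gamma columns, percent) and `grid` (the parameter
#'   values). Ties are broken toward smaller beta, then smaller gamma.
#' @export
grid_search <- function(own, generic = list(), grid_step = 0.1, alpha = 2,
                        mode = c("cv", "holdout"), folds = 5, k = 5,
                        kernel = "radial", cost = 1, seed = 1) {
  mode <- match.arg(mode)
  vals <- seq(0, 1, by = grid_step)
  summaries <- class_summaries(own, generic)
  train_trials <- dataset_trials(own, "train")
  train_labels <- dataset_labels(own, "train")
  train_cov <- lapply(train_trials, centered_covariance)
  if (mode == "holdout") {
    test_trials <- dataset_trials(own, "test")
    test_labels <- dataset_labels(own, "test")
    if (length(test_trials) == 0) stop("holdout mode requires test trials")
    test_cov <- lapply(test_trials, centered_covariance)
  } else {
    fold_id <- stratified_folds(train_labels, folds, seed)
  }
  acc <- matrix(NA_real_, length(vals), length(vals),
                dimnames = list(beta = vals, gamma = vals))
  for (i in seq_along(vals)) {
    for (j in seq_along(vals)) {
      cell <- tryCatch({
        cfg <- rcsp_config(vals[i], vals[j], alpha)
        bank <- bank_from_summaries(summaries, cfg)
        fx <- t(vapply(train_cov, features_from_cov, bank = bank,
                       numeric(length(bank$filters) * 2 * alpha)))
        if (mode == "holdout") {
          ft <- t(vapply(test_cov, features_from_cov, bank = bank,
                         numeric(ncol(fx))))
          model <- knnsvm_fit(fx, train_labels, k = k, kernel = kernel,
                              cost = cost)
          mean(predict(model, ft) == test_labels)
        } else {
          cv_accuracy(fx, train_labels, fold_id, k, kernel, cost)
        }
      }, error = function(e) {
        warning("grid cell (beta=", vals[i], ", gamma=", vals[j],
                ") failed: ", conditionMessage(e))
        0
      })
      acc[i, j] <- 100 * cell
    }
  }
  best_idx <- which(acc == max(acc), arr.ind = TRUE)
  best_idx <- best_idx[order(best_idx[, 1], best_idx[, 2]), , drop = FALSE][1, ]
  list(best = rcsp_config(vals[best_idx[1]], vals[best_idx[2]], alpha),
       accuracy = acc, grid = vals)
}

# Deterministic stratified fold assignment.
stratified_folds <- function(labels, folds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

cv_accuracy <- function(features, labels, fold_id, k, kernel, cost) {
  correct <- 0
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    model <- knnsvm_fit(features[tr, , drop = FALSE], labels[tr],
                        k = min(k, sum(tr)), kernel = kernel, cost = cost)
    pred <- predict(model, features[!tr, , drop = FALSE])
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}
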