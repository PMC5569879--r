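#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations and the master seed. Stage seeds are
#' derived from the master seed by a fixed counter scheme (`seed + 0`
#' drives data generation, `seed + 1` the cross-validation folds), so
#' adding a stage never perturbs earlier ones.
#'
#' @param synthetic a [synthetic_config()]; its seed field is overridden
#'   by `seed`.
#' @param fspec a [filter_spec()].
#' @param wspec a [wavelet_spec()].
#' @param rcsp an [rcsp_config()] used when `grid = FALSE`.
#' @param window analysis window (seconds) cut from each trial after
#'   filtering.
#' @param notch apply the notch stage?
#' @param wcca apply wCCA artifact removal?
#' @param grid run the (beta, gamma) grid search per subject instead of
#'   using `rcsp` as-is?
#' @param grid_step grid spacing when `grid = TRUE`.
#' @param grid_mode "cv" or "holdout" (see [grid_search()]).
#' @param k,kernel,cost classifier hyperparameters.
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            fspec = filter_spec(),
                            wspec = wavelet_spec(),
                            rcsp = rcsp_config(beta = 0.1, gamma = 0.1),
                            window = c(2, 7), notch = TRUE, wcca = TRUE,
                            grid = FALSE, grid_step = 0.1,
                            grid_mode = "cv",
                            k = 5, kernel = "radial", cost = 1, seed = 1) {
  structure(list(synthetic = synthetic, fspec = fspec, wspec = wspec,
                 rcsp = rcsp, window = window, notch = notch, wcca = wcca,
                 grid = grid, grid_step = grid_step, grid_mode = grid_mode,
                 k = k, kernel = kernel, cost = cost,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full decoding pipeline
#'
#' Stages, in order: synthetic data generation (or user-supplied
#' datasets), temporal filtering, cropping to the imagery window, wCCA +
#' midline wavelet denoising, per-subject R-CSP filter-bank fitting with
#' generic learning (optionally preceded by the regularization grid
#' search), feature extraction, KNN-SVM training, and evaluation on each
#' subject's test split. Identical configuration and seed give identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @param datasets optional list of [eeg_dataset()] objects; when NULL
#'   the synthetic generator provides them.
#' @param montage the [montage()].
#' @param verbose print stage progress?
#' @return Object of class `pipeline_report`: per-subject confusion
#'   matrices, selected configurations, feature dimension, mean accuracy
#'   and the seed.
#' @export
run_pipeline <- function(config = pipeline_config(), datasets = NULL,
                         montage = default_montage(), verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S"),
                                            " [pipeline] ", ...)
  if (is.null(datasets)) {
    say("simulate: ", config$synthetic$n_subjects, " subjects")
    config$synthetic$seed <- config$seed
    datasets <- generate_dataset(config$synthetic, montage)
  }
  say("preprocess: filtering, window [", config$window[1], ", ",
      config$window[2], ") s, wcca = ", config$wcca)
  datasets <- lapply(datasets, preprocess_dataset, montage = montage,
                     fspec = config$fspec, wspec = config$wspec,
                     window = config$window, notch = config$notch,
                     wcca = config$wcca)
  subjects <- vector("list", length(datasets))
  for (s in seq_along(datasets)) {
    own <- datasets[[s]]
    generic <- datasets[-s]
    cfg <- config$rcsp
    grid_result <- NULL
    if (config$grid) {
      say("grid search: subject ", own$subject_id)
      grid_result <- grid_search(own, generic, grid_step = config$grid_step,
                                 alpha = config$rcsp$alpha,
                                 mode = config$grid_mode, k = config$k,
                                 kernel = config$kernel, cost = config$cost,
                                 seed = config$seed + 1)
      cfg <- grid_result$best
    }
    say("fit-rcsp + train + evaluate: subject ", own$subject_id,
        sprintf(" (beta = %.2f, gamma = %.2f)", cfg$beta, cfg$gamma))
    bank <- build_filter_bank(own, generic, cfg)
    train_x <- feature_matrix(own, bank, "train")
    test_x <- feature_matrix(own, bank, "test")
    model <- knnsvm_fit(train_x, attr(train_x, "labels"), k = config$k,
                        kernel = config$kernel, cost = config$cost)
    confusion <- evaluate_features(model, test_x, attr(test_x, "labels"))
    subjects[[s]] <- list(subject_id = own$subject_id, rcsp = cfg,
                          grid = grid_result, bank = bank, model = model,
                          train_features = train_x, test_features = test_x,
                          confusion = confusion)
  }
  acc <- vapply(subjects, function(s) s$confusion$overall_accuracy,
                numeric(1))
  structure(list(subjects = subjects, mean_accuracy = mean(acc),
                 per_subject_accuracy = stats::setNames(
                   acc, vapply(subjects, `[[`, character(1), "subject_id")),
                 feature_dim = ncol(subjects[[1]]$train_features),
                 seed = config$seed, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$seed, "): ", length(x$subjects),
      " subjects, ", x$feature_dim, "-dimensional features\n", sep = "")
  for (s in x$subjects)
    cat(sprintf("  %s: accuracy %.1f%% (beta = %.2f, gamma = %.2f)\n",
                s$subject_id, 100 * s$confusion$overall_accuracy,
                s$rcsp$beta, s$rcsp$gamma))
  cat(sprintf("Mean accuracy: %.1f%%\n", 100 * x$mean_accuracy))
  invisible(x)
}
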