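#' Construct a labelled EEG trial
#'
#' A trial holds the EEG channel-by-sample matrix (microvolts), the
#' time-locked VEOG trace, the motor-imagery state label and the sampling
#' rate.
#'
#' @param data numeric matrix, EEG channels x samples, with channel names
#'   as row names.
#' @param veog numeric vector of VEOG samples, same length as `ncol(data)`.
#' @param label one of the four state labels (see [class_levels()]).
#' @param fs sampling rate in Hz.
#' @return Object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, veog, label, fs) {
  data <- as.matrix(data)
  if (ncol(data) < 1L) stop("trial must contain at least one sample")
  if (length(veog) != ncol(data))
    stop("veog length must equal the trial sample count")
  if (!all(is.finite(data)) || !all(is.finite(veog)))
    stop("trial contains non-finite values")
  label <- as.character(label)
  if (!label %in% class_levels())
    stop("label must be one of: ", paste(class_levels(), collapse = ", "))
  structure(list(data = data, veog = as.numeric(veog), label = label,
                 fs = as.numeric(fs)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("EEG trial [%s]: %d channels x %d samples (%.2f s @ %g Hz)\n",
              x$label, nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Construct a per-subject dataset of labelled trials
#'
#' @param subject_id identifier for the subject.
#' @param trials list of [eeg_trial()] objects.
#' @param split character vector ("train"/"test"), one tag per trial.
#' @return Object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(subject_id, trials, split) {
  if (length(split) != length(trials))
    stop("split must tag every trial")
  if (!all(split %in% c("train", "test")))
    stop("split tags must be 'train' or 'test'")
  structure(list(subject_id = subject_id, trials = trials,
                 split = as.character(split)),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  lab <- vapply(x$trials, function(t) t$label, character(1))
  cat("EEG dataset, subject", x$subject_id, "-", length(x$trials), "trials (",
      sum(x$split == "train"), "train /", sum(x$split == "test"), "test )\n")
  print(table(label = lab, split = x$split))
  invisible(x)
}

#' Trial labels of a dataset
#' @param dataset an `eeg_dataset`.
#' @param split optional: restrict to "train" or "test" trials.
#' @return character vector of labels.
#' @export
dataset_labels <- function(dataset, split = NULL) {
  keep <- if (is.null(split)) rep(TRUE, length(dataset$trials))
          else dataset$split == split
  vapply(dataset$trials[keep], function(t) t$label, character(1))
}

#' Subset the trials of a dataset by split tag
#' @param dataset an `eeg_dataset`.
#' @param split "train" or "test".
#' @return list of `eeg_trial` objects.
#' @export
dataset_trials <- function(dataset, split = NULL) {
  if (is.null(split)) return(dataset$trials)
  dataset$trials[dataset$split == split]
}

#' Crop a trial to a time window
#'
#' Extracts the half-open window `[start, end)` seconds, measured from the
#' start of the trial (sample 0). The default window is the motor-imagery
#' period of the trial paradigm.
#'
#' @param trial an `eeg_trial`.
#' @param window numeric length-2, start and end in seconds.
#' @return Cropped `eeg_trial`.
#' @export
crop_trial <- function(trial, window = c(2, 7)) {
  idx <- window_indices(window, trial$fs, ncol(trial$data))
  eeg_trial(trial$data[, idx, drop = FALSE], trial$veog[idx],
            trial$label, trial$fs)
}

# Half-open sample window [start, end) with 0-based sample semantics:
# sample k covers time k / fs. Errors on empty or out-of-range windows.
window_indices <- function(window, fs, n_samples) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be (start, end) seconds with end > start")
  first <- round(window[1] * fs)
  len <- round((window[2] - window[1]) * fs)
  if (first < 0 || first + len > n_samples)
    stop("window [", window[1], ", ", window[2], ") extends outside the trial")
  seq.int(first + 1L, first + len)
}
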