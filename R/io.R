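#' Construct a continuous multichannel recording
#'
#' @param data numeric matrix, channels x samples (microvolts), row names =
#'   channel names (all montage EEG channels plus the VEOG channel).
#' @param montage a [montage()].
#' @param events data.frame with columns `onset_sample` (0-based sample
#'   index of trial onset, strictly increasing) and `label`.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, montage, events) {
  data <- as.matrix(data)
  expected <- c(montage$eeg_channels, montage$veog_channel)
  if (nrow(data) != length(expected))
    stop("recording must have one row per montage channel (EEG + VEOG)")
  if (is.null(rownames(data))) rownames(data) <- expected
  events <- as.data.frame(events)
  if (!all(c("onset_sample", "label") %in% names(events)))
    stop("events must have columns onset_sample and label")
  if (nrow(events) > 1 && any(diff(events$onset_sample) <= 0))
    stop("event onsets must be strictly increasing")
  if (nrow(events) > 0 &&
      (min(events$onset_sample) < 0 || max(events$onset_sample) >= ncol(data)))
    stop("event onsets must lie within the recording")
  structure(list(data = data, montage = montage, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s @ %g Hz), %d events\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$montage$fs,
              x$montage$fs, nrow(x$events)))
  invisible(x)
}

events_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_events.tsv")
}

#' Write a recording in the delimited text dialect
#'
#' The dialect is a UTF-8 tab-separated file with one header row of
#' channel names and one column per channel (samples as rows), paired with
#' a sidecar events file `<stem>_events.tsv` holding `onset_s` and `label`
#' columns.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path; the events sidecar is derived from it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  df <- as.data.frame(t(recording$data))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  ev <- data.frame(onset_s = recording$events$onset_sample / recording$montage$fs,
                   label = recording$events$label)
  utils::write.table(ev, events_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_delimited_recording <- function(path, montage) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, fileEncoding = "UTF-8")
  mat <- t(as.matrix(df))
  mat <- match_montage_rows(mat, montage)
  evp <- events_path(path)
  events <- data.frame(onset_sample = integer(0), label = character(0))
  if (file.exists(evp)) {
    ev <- utils::read.table(evp, header = TRUE, sep = "\t",
                            fileEncoding = "UTF-8")
    events <- data.frame(onset_sample = round(ev$onset_s * montage$fs),
                         label = as.character(ev$label))
  }
  eeg_recording(mat, montage, events)
}

# Case-insensitive channel matching, rows reordered to montage order.
match_montage_rows <- function(mat, montage) {
  expected <- c(montage$eeg_channels, montage$veog_channel)
  have <- rownames(mat)
  idx <- match(toupper(expected), toupper(have))
  if (anyNA(idx))
    stop("montage mismatch: missing channels ",
         paste(expected[is.na(idx)], collapse = ", "))
  out <- mat[idx, , drop = FALSE]
  rownames(out) <- expected
  out
}

#' Load a continuous recording from disk
#'
#' @param path path to the recording file.
#' @param format "delimited" (tab-separated dialect of
#'   [write_recording()]) or "edf".
#' @param montage the [montage()] to resolve channels against
#'   (case-insensitive); rows of the result are in montage order and in
#'   microvolts.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("delimited", "edf"),
                           montage = default_montage()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: ", path)
  switch(format,
         delimited = read_delimited_recording(path, montage),
         edf = read_edf(path, montage))
}

#' Epoch a continuous recording into labelled trials
#'
#' Cuts one trial per event using a half-open window `[start, end)`
#' seconds relative to the event onset. The VEOG channel is split out of
#' the EEG matrix. Events whose window would run past the end of the
#' recording raise a "truncated epoch" warning and are dropped.
#'
#' @param recording an [eeg_recording()].
#' @param window numeric length-2, (start, end) seconds relative to onset.
#' @return List of [eeg_trial()] objects.
#' @export
epoch_trials <- function(recording, window = c(2, 7)) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be (start, end) seconds with end > start")
  if (nrow(recording$events) == 0) stop("recording has no events")
  fs <- recording$montage$fs
  len <- round((window[2] - window[1]) * fs)
  nsamp <- ncol(recording$data)
  veog_row <- recording$montage$veog_channel
  eeg_rows <- recording$montage$eeg_channels
  trials <- list()
  truncated <- character(0)
  for (i in seq_len(nrow(recording$events))) {
    onset <- recording$events$onset_sample[i]
    first <- onset + round(window[1] * fs)
    if (first < 0 || first + len > nsamp) {
      truncated <- c(truncated, sprintf("event %d (onset %.3f s)", i, onset / fs))
      next
    }
    idx <- seq.int(first + 1L, first + len)
    trials[[length(trials) + 1L]] <-
      eeg_trial(recording$data[eeg_rows, idx, drop = FALSE],
                recording$data[veog_row, idx],
                recording$events$label[i], fs)
  }
  if (length(truncated) > 0)
    warning("truncated epoch for: ", paste(truncated, collapse = "; "))
  trials
}

#' Concatenate a dataset of trials into a continuous recording
#'
#' Trials are laid end to end with an event at each trial onset, so that
#' [epoch_trials()] with a window covering the full trial recovers them.
#'
#' @param dataset an [eeg_dataset()]; all trials must share length and fs.
#' @return An [eeg_recording()].
#' @export
dataset_to_recording <- function(dataset, montage = default_montage()) {
  stopifnot(length(dataset$trials) > 0)
  tlen <- ncol(dataset$trials[[1]]$data)
  mats <- lapply(dataset$trials, function(t) {
    if (ncol(t$data) != tlen) stop("trials differ in length")
    rbind(t$data, t$veog)
  })
  data <- do.call(cbind, mats)
  rownames(data) <- c(montage$eeg_channels, montage$veog_channel)
  events <- data.frame(
    onset_sample = (seq_along(dataset$trials) - 1L) * tlen,
    label = dataset_labels(dataset))
  eeg_recording(data, montage, events)
}

#' Write each subject dataset in the delimited dialect
#'
#' One recording file and one events sidecar per subject, named
#' `subject_<id>.tsv`, plus a `metadata.json` recording the seed and
#' split layout.
#'
#' @param datasets list of [eeg_dataset()] objects.
#' @param dir output directory (created if absent).
#' @param seed the generator seed to record in the metadata.
#' @return Vector of written recording paths, invisibly.
#' @export
write_datasets <- function(datasets, dir, montage = default_montage(),
                           seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ds in datasets) {
    p <- file.path(dir, paste0("subject_", ds$subject_id, ".tsv"))
    write_recording(dataset_to_recording(ds, montage), p)
    utils::write.table(
      data.frame(trial = seq_along(ds$trials),
                 label = dataset_labels(ds), split = ds$split),
      file.path(dir, paste0("subject_", ds$subject_id, "_split.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(seed = seed, subjects = vapply(datasets, function(d)
    as.character(d$subject_id), character(1)), fs = montage$fs)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(paths)
}
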