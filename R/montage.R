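#' Electrode montage for the 14-channel sensorimotor recording layout
#'
#' A montage records the EEG channel names, their partition into a left
#' hemispheric group, a mirrored right hemispheric group and a midline
#' (central) group, plus the vertical electrooculogram (VEOG) channel and
#' the sampling rate. The hemispheric groups are ordered so that element
#' `i` of `right_group` is the anatomical mirror of element `i` of
#' `left_group`; that pairing is what the cross-hemisphere canonical
#' correlation denoiser relies on.
#'
#' @param eeg_channels character vector of all EEG channel names, in
#'   recording order.
#' @param left_group,right_group character vectors of equal length giving
#'   the mirrored hemispheric channels (index-aligned).
#' @param central_group character vector of midline channels.
#' @param veog_channel name of the VEOG channel.
#' @param fs sampling rate in Hz.
#' @return An object of class `montage`.
#' @examples
#' m <- default_montage()
#' m$fs
#' @export
montage <- function(eeg_channels, left_group, right_group, central_group,
                    veog_channel, fs) {
  eeg_channels <- as.character(eeg_channels)
  m <- structure(
    list(eeg_channels = eeg_channels,
         left_group = as.character(left_group),
         right_group = as.character(right_group),
         central_group = as.character(central_group),
         veog_channel = as.character(veog_channel),
         fs = as.numeric(fs)),
    class = "montage")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  if (length(m$left_group) != length(m$right_group))
    stop("left_group and right_group must have equal length (mirror pairing)")
  grp <- c(m$left_group, m$right_group, m$central_group)
  if (anyDuplicated(grp))
    stop("hemispheric/central groups overlap: ",
         paste(grp[duplicated(grp)], collapse = ", "))
  if (!setequal(grp, m$eeg_channels))
    stop("left/right/central groups must partition eeg_channels")
  if (length(m$veog_channel) != 1L || m$veog_channel %in% m$eeg_channels)
    stop("veog_channel must be a single channel outside eeg_channels")
  if (!is.finite(m$fs) || m$fs <= 0) stop("fs must be positive")
  invisible(m)
}

#' Default 14-channel + VEOG montage
#'
#' Six symmetric electrode pairs over the sensorimotor and parietal
#' cortex (T7/T8, P3/P4, P7/P8, CP3/CP4, FC3/FC4, C3/C4), two midline
#' electrodes (FZ, CZ) and a bipolar VEOG channel, sampled at 256 Hz.
#'
#' @param fs sampling rate in Hz (default 256).
#' @return A `montage` object.
#' @export
default_montage <- function(fs = 256) {
  left <- c("T7", "P3", "P7", "CP3", "FC3", "C3")
  right <- c("T8", "P4", "P8", "CP4", "FC4", "C4")
  montage(eeg_channels = c(left, right, "FZ", "CZ"),
          left_group = left, right_group = right,
          central_group = c("FZ", "CZ"),
          veog_channel = "VEOG", fs = fs)
}

#' @export
print.montage <- function(x, ...) {
  cat("EEG montage:", length(x$eeg_channels), "EEG channels + VEOG, fs =",
      x$fs, "Hz\n")
  cat("  left :", paste(x$left_group, collapse = " "), "\n")
  cat("  right:", paste(x$right_group, collapse = " "), "\n")
  cat("  mid  :", paste(x$central_group, collapse = " "), "\n")
  invisible(x)
}

#' Canonical class labels
#'
#' The four motor-imagery states in the fixed canonical order used for
#' confusion matrices, pairwise filter banks and tie-breaking: resting
#' state (R), right foot (RF), left hand (LH), right shoulder (RS).
#'
#' @return Character vector of the four state labels.
#' @export
class_levels <- function() c("R", "RF", "LH", "RS")

#' Unordered class pairs in canonical order
#'
#' The six unordered pairs of the four states, ordered by the canonical
#' class order. This fixed order indexes the spatial filter bank and the
#' blocks of the concatenated feature vector.
#'
#' @return 2-column character matrix with one row per pair.
#' @export
class_pairs <- function() {
  lv <- class_levels()
  t(utils::combn(lv, 2))
}
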