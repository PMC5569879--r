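#' Temporal filter specification
#'
#' Parameters of the temporal preprocessing front end: a 50 Hz notch
#' against power-line interference and a Butterworth band-pass isolating
#' the 8-30 Hz mu/beta band that carries motor-imagery modulations.
#'
#' @param band numeric length-2, band-pass edges in Hz.
#' @param order Butterworth prototype order (a band-pass of order `order`
#'   has `2 * order` poles).
#' @param notch_freq notch centre frequency in Hz.
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @param zero_phase apply filters forward and backward (no phase
#'   distortion, squared magnitude response)?
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(band = c(8, 30), order = 4, notch_freq = 50,
                        notch_q = 30, zero_phase = TRUE) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must satisfy 0 < low < high")
  if (order < 1) stop("order must be >= 1")
  structure(list(band = as.numeric(band), order = as.integer(order),
                 notch_freq = as.numeric(notch_freq),
                 notch_q = as.numeric(notch_q),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Direct-form IIR applied along the rows of a channels x samples matrix.
# stats::filter runs column-wise, so the matrix is transposed once.
iir_rows <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  xt <- t(x)
  nb <- length(b)
  if (nb > 1) {
    padded <- rbind(matrix(0, nb - 1, ncol(xt)), xt)
    v <- stats::filter(padded, b, method = "convolution", sides = 1)
    v <- v[nb:(nrow(padded)), , drop = FALSE]
  } else {
    v <- xt * b
  }
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1], method = "recursive")
  }
  t(matrix(v, nrow = nrow(xt)))
}

# Zero-phase filtering with odd-reflection end padding (attenuates edge
# transients of the forward-backward pass).
filtfilt_rows <- function(b, a, x) {
  n <- ncol(x)
  pad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 128L))
  left <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE]
  ext <- cbind(left, x, right)
  y <- iir_rows(b, a, ext)
  y <- y[, ncol(y):1, drop = FALSE]
  y <- iir_rows(b, a, y)
  y <- y[, ncol(y):1, drop = FALSE]
  y[, (pad + 1):(pad + n), drop = FALSE]
}

apply_iir <- function(b, a, x, zero_phase) {
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  out <- if (zero_phase) filtfilt_rows(b, a, xm) else iir_rows(b, a, xm)
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  out
}

# Second-order IIR notch (constrained pole-zero placement): unit gain at
# DC and Nyquist, zero at the notch frequency.
notch_coefficients <- function(freq, fs, q) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter against power-line interference
#'
#' @param x numeric matrix (channels x samples) or vector.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered signal, same shape as `x`.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$notch_freq)
    stop("fs must exceed twice the notch frequency")
  co <- notch_coefficients(spec$notch_freq, fs, spec$notch_q)
  out <- apply_iir(co$b, co$a, x, spec$zero_phase)
  if (is.matrix(x)) out else drop(out)
}

#' Butterworth band-pass filter
#'
#' Isolates the band `spec$band` (default 8-30 Hz). In zero-phase mode the
#' filter is applied forward and backward.
#'
#' @inheritParams notch_filter
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_butterworth <- function(x, fs, spec = filter_spec()) {
  if (spec$band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  bt <- signal::butter(spec$order, spec$band / (fs / 2), type = "pass")
  out <- apply_iir(bt$b, bt$a, x, spec$zero_phase)
  if (is.matrix(x)) out else drop(out)
}

#' Apply the temporal front end to a trial
#'
#' Notch (optional) then band-pass, applied jointly to the EEG channels
#' and the VEOG trace so all downstream stages see the same pass band.
#'
#' @param trial an [eeg_trial()].
#' @param spec a [filter_spec()].
#' @param notch apply the notch stage?
#' @return Filtered `eeg_trial`.
#' @export
filter_trial <- function(trial, spec = filter_spec(), notch = TRUE) {
  full <- rbind(trial$data, trial$veog)
  if (notch) full <- notch_filter(full, trial$fs, spec)
  full <- bandpass_butterworth(full, trial$fs, spec)
  eeg_trial(full[-nrow(full), , drop = FALSE], full[nrow(full), ],
            trial$label, trial$fs)
}
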