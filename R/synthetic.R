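#' Configuration of the synthetic motor-imagery EEG generator
#'
#' The generator emulates the statistical structure the decoding pipeline
#' assumes: 14-channel sensorimotor EEG plus a VEOG channel at 256 Hz,
#' 9-second trials whose motor-imagery period spans seconds 2-7,
#' class-dependent 8-30 Hz band-power patterns over distinct channel
#' groups, and large raised-cosine blink transients that propagate from
#' frontal to posterior electrodes with a strong VEOG projection.
#'
#' The class-to-channel map follows sensorimotor physiology: left-hand
#' imagery modulates the right hemisphere (C4/FC4/CP4), right-shoulder
#' imagery the left hemisphere (C3/FC3/CP3), right-foot imagery the
#' midline (FZ/CZ), and rest shows posterior idle rhythm (P3/P4/P7/P8).
#' `gain` is the fractional excess of 8-30 Hz band power on a class's
#' active channels over the background during the imagery window (gain 1
#' means twice the background band power).
#'
#' @param n_subjects number of subjects (default 5).
#' @param trials_per_state trials per class per subject (default 60).
#' @param train_per_state trials per class tagged "train" (default 50;
#'   the remainder are "test").
#' @param fs sampling rate, Hz.
#' @param trial_len trial length, seconds.
#' @param mi_window imagery window in seconds within the trial.
#' @param class_pattern_map named list (one entry per class) of
#'   `list(channels =, gain =)`.
#' @param background_noise_sd standard deviation of the 1/f background
#'   noise, microvolts.
#' @param blink_rate blink events per second (Poisson).
#' @param blink_amplitude blink peak amplitude on the VEOG channel,
#'   microvolts.
#' @param blink_width blink duration, seconds.
#' @param frontal_decay named vector of per-channel blink projection
#'   weights in `[0, 1]`, largest frontally.
#' @param veog_noise_sd measurement noise on the VEOG channel, microvolts.
#' @param line_noise_amp amplitude of an optional 50 Hz mains component,
#'   microvolts (0 disables it; used to exercise the notch stage).
#' @param seed integer RNG seed; the full multi-subject dataset is a
#'   deterministic function of the configuration.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 5, trials_per_state = 60,
                             train_per_state = 50, fs = 256, trial_len = 9,
                             mi_window = c(2, 7),
                             class_pattern_map = default_class_patterns(),
                             background_noise_sd = 15,
                             blink_rate = 0.25, blink_amplitude = 200,
                             blink_width = 0.35,
                             frontal_decay = default_frontal_decay(),
                             veog_noise_sd = 2, line_noise_amp = 0,
                             seed = 1) {
  stopifnot(n_subjects >= 1, trials_per_state >= 1,
            train_per_state >= 1, train_per_state <= trials_per_state,
            fs > 0, trial_len > 0,
            background_noise_sd >= 0, blink_rate >= 0,
            blink_amplitude >= 0, blink_width > 0, veog_noise_sd >= 0,
            line_noise_amp >= 0)
  if (!setequal(names(class_pattern_map), class_levels()))
    stop("class_pattern_map must have exactly the classes ",
         paste(class_levels(), collapse = ", "))
  if (any(frontal_decay < 0 | frontal_decay > 1))
    stop("frontal_decay values must lie in [0, 1]")
  structure(list(n_subjects = n_subjects,
                 trials_per_state = trials_per_state,
                 train_per_state = train_per_state,
                 fs = fs, trial_len = trial_len, mi_window = mi_window,
                 class_pattern_map = class_pattern_map,
                 background_noise_sd = background_noise_sd,
                 blink_rate = blink_rate,
                 blink_amplitude = blink_amplitude,
                 blink_width = blink_width,
                 frontal_decay = frontal_decay,
                 veog_noise_sd = veog_noise_sd,
                 line_noise_amp = line_noise_amp,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_class_patterns <- function() {
  list(R = list(channels = c("P3", "P4", "P7", "P8"), gain = 1),
       RF = list(channels = c("FZ", "CZ"), gain = 1),
       LH = list(channels = c("C4", "FC4", "CP4"), gain = 1),
       RS = list(channels = c("C3", "FC3", "CP3"), gain = 1))
}

#' @rdname synthetic_config
#' @export
default_frontal_decay <- function() {
  c(FC3 = 0.5, FC4 = 0.5, FZ = 0.6, C3 = 0.3, C4 = 0.3, CZ = 0.35,
    CP3 = 0.2, CP4 = 0.2, T7 = 0.15, T8 = 0.15, P3 = 0.1, P4 = 0.1,
    P7 = 0.05, P8 = 0.05)
}

#' Generate a train of blink pulses
#'
#' Raised-cosine pulses (smooth, essentially band-limited below 8 Hz) at
#' Poisson-distributed onsets; overlapping pulses add linearly.
#'
#' @param duration signal duration, seconds.
#' @param rate blink rate, events per second.
#' @param amplitude pulse peak amplitude, microvolts.
#' @param width pulse width, seconds.
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed; when given, the train is a
#'   deterministic function of the arguments (the caller's RNG state is
#'   preserved).
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
generate_blink_train <- function(duration, rate, amplitude, width, fs,
                                 seed = NULL) {
  stopifnot(duration > 0, fs > 0, rate >= 0, amplitude >= 0, width > 0)
  n <- round(duration * fs)
  out <- numeric(n)
  if (rate == 0 || amplitude == 0) return(out)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  n_events <- stats::rpois(1, rate * duration)
  if (n_events == 0) return(out)
  onsets <- sort(stats::runif(n_events, 0, duration - width))
  pulse_len <- round(width * fs)
  pulse <- amplitude * 0.5 * (1 - cos(2 * pi * seq_len(pulse_len) / pulse_len))
  for (on in onsets) {
    i0 <- round(on * fs)
    idx <- (i0 + 1):min(i0 + pulse_len, n)
    out[idx] <- out[idx] + pulse[seq_along(idx)]
  }
  out
}

# 1/f ("pink-ish") background noise synthesized in the frequency domain
# with a 1 Hz flattening floor, scaled to the requested time-domain sd.
# Returns an n_samples x n_signals matrix.
pink_noise <- function(n, n_signals, fs, sd) {
  if (sd == 0) return(matrix(0, n, n_signals))
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  shape <- 1 / sqrt(pmax(freqs, 1))
  shape[1] <- 0  # no DC
  nf <- length(shape)
  re <- matrix(stats::rnorm(nf * n_signals), nf, n_signals) * shape
  im <- matrix(stats::rnorm(nf * n_signals), nf, n_signals) * shape
  spec <- matrix(0i, n, n_signals)
  spec[seq_len(nf), ] <- complex(real = re, imaginary = im)
  # Re() of the inverse FFT implicitly Hermitian-symmetrizes the
  # spectrum; the requested sd is imposed afterwards.
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/") * sd
  x
}

# Fraction of the background variance lying in the band (closed form from
# the synthesis spectrum above).
pink_band_fraction <- function(n, fs, band) {
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  p <- 1 / pmax(freqs, 1)
  p[1] <- 0
  sum(p[freqs >= band[1] & freqs <= band[2]]) / sum(p)
}

#' Generate labelled multi-subject synthetic EEG datasets
#'
#' Each trial is the sum of 1/f background noise, class-specific
#' amplitude-modulated mu (10 Hz) and beta (22 Hz) oscillations on the
#' class's active channels during the imagery window, and a blink train
#' projected onto the EEG channels through the frontal decay profile. The
#' VEOG channel carries the blink train plus measurement noise. The
#' oscillation amplitude is calibrated analytically so that active
#' channels exceed the background 8-30 Hz band power by the configured
#' gain during the imagery window.
#'
#' @param config a [synthetic_config()].
#' @param montage the [montage()] to generate for.
#' @return List of [eeg_dataset()] objects, one per subject, labelled
#'   `S1 ... Sn`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             montage = default_montage()) {
  set.seed(config$seed)
  n <- round(config$trial_len * config$fs)
  chans <- montage$eeg_channels
  nch <- length(chans)
  decay <- config$frontal_decay[chans]
  decay[is.na(decay)] <- 0
  t_axis <- (seq_len(n) - 1) / config$fs
  mi <- t_axis >= config$mi_window[1] & t_axis < config$mi_window[2]
  env <- numeric(n)
  # Hann envelope over the imagery window (mean square 3/8)
  env[mi] <- 0.5 * (1 - cos(2 * pi * seq_len(sum(mi)) / sum(mi)))
  band_frac <- pink_band_fraction(n, config$fs, c(8, 30))
  p_band <- config$background_noise_sd^2 * band_frac
  lapply(seq_len(config$n_subjects), function(s) {
    labels <- rep(class_levels(), each = config$trials_per_state)
    split <- rep(rep(c("train", "test"),
                     c(config$train_per_state,
                       config$trials_per_state - config$train_per_state)),
                 length(class_levels()))
    trials <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      lab <- labels[i]
      bg <- t(pink_noise(n, nch, config$fs, config$background_noise_sd))
      rownames(bg) <- chans
      pat <- config$class_pattern_map[[lab]]
      if (pat$gain > 0 && length(pat$channels) > 0) {
        # oscillation band power = amp^2 * mean(env^2) * 1/2 = gain * p_band
        amp <- sqrt(pat$gain * p_band / (3 / 8) * 2)
        for (ch in intersect(pat$channels, chans)) {
          osc <- amp * env *
            (sin(2 * pi * 10 * t_axis + stats::runif(1, 0, 2 * pi)) +
             sin(2 * pi * 22 * t_axis + stats::runif(1, 0, 2 * pi))) /
            sqrt(2)
          bg[ch, ] <- bg[ch, ] + osc
        }
      }
      blink <- generate_blink_train(config$trial_len, config$blink_rate,
                                    config$blink_amplitude,
                                    config$blink_width, config$fs)
      bg <- bg + outer(decay, blink)
      if (config$line_noise_amp > 0)
        bg <- bg + matrix(config$line_noise_amp *
                            sin(2 * pi * 50 * t_axis),
                          nch, n, byrow = TRUE)
      veog <- blink + stats::rnorm(n, sd = config$veog_noise_sd)
      trials[[i]] <- eeg_trial(bg, veog, lab, config$fs)
    }
    ord <- sample(seq_along(trials))
    eeg_dataset(paste0("S", s), trials[ord], split[ord])
  })
}
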