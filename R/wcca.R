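#' Remove ocular artifacts from the symmetric channels by wCCA
#'
#' Builds the two augmented hemispheric blocks `X = [left 6 channels;
#' VEOG]` and `Y = [right 6 channels; VEOG]`, centres them, fits a
#' canonical correlation model and wavelet-threshold-denoises only the
#' first canonical pair `u1`, `v1` (the maximally correlated shared
#' component, dominated by the ocular artifact because the VEOG trace is
#' present in both blocks). The blocks are then reconstructed through the
#' inverse of the canonical basis, the row means are restored, and the
#' twelve symmetric channels of the trial are replaced by the cleaned
#' rows; midline channels and the stored VEOG trace are untouched.
#'
#' @param trial an [eeg_trial()] containing the montage's symmetric
#'   channels.
#' @param montage the [montage()] describing the hemispheric groups.
#' @param spec a [wavelet_spec()]; the default suppress-above rule zeroes
#'   large-magnitude coefficients (the artifact transients) and keeps the
#'   small ones (residual EEG in the shared component).
#' @return List with `trial` (cleaned trial) and `report`, a
#'   `denoise_report` holding the first canonical correlation, the
#'   fraction of first-pair energy removed and per-channel VEOG
#'   correlations before and after.
#' @export
wcca_denoise <- function(trial, montage = default_montage(),
                         spec = wavelet_spec()) {
  sym <- c(montage$left_group, montage$right_group)
  if (!all(sym %in% rownames(trial$data)))
    stop("trial lacks symmetric channels: ",
         paste(setdiff(sym, rownames(trial$data)), collapse = ", "))
  x <- rbind(trial$data[montage$left_group, , drop = FALSE],
             VEOG = trial$veog)
  y <- rbind(trial$data[montage$right_group, , drop = FALSE],
             VEOG = trial$veog)
  cx <- center_rows(x); cy <- center_rows(y)
  model <- cca_fit(cx$centered, cy$centered)
  if (kappa(model$A, exact = FALSE) > 1e10 ||
      kappa(model$B, exact = FALSE) > 1e10)
    stop("non-invertible canonical basis")
  u <- crossprod(model$A, cx$centered)
  v <- crossprod(model$B, cy$centered)
  u1 <- u[1, ]; v1 <- v[1, ]
  u[1, ] <- wavelet_denoise(u1, spec)
  v[1, ] <- wavelet_denoise(v1, spec)
  xnew <- solve(t(model$A), u) + cx$means
  ynew <- solve(t(model$B), v) + cy$means
  out <- trial
  out$data[montage$left_group, ] <- xnew[seq_along(montage$left_group), ]
  out$data[montage$right_group, ] <- ynew[seq_along(montage$right_group), ]
  pre <- channel_veog_correlation(trial)
  post <- channel_veog_correlation(out)
  energy <- function(orig, den) {
    e <- sum(orig^2)
    if (e == 0) 0 else max(0, 1 - sum(den^2) / e)
  }
  report <- structure(
    list(rho1 = model$rho[1],
         energy_removed = c(u1 = energy(u1, u[1, ]), v1 = energy(v1, v[1, ])),
         veog_correlation = data.frame(channel = rownames(trial$data),
                                       pre = pre, post = post,
                                       row.names = NULL)),
    class = "denoise_report")
  list(trial = out, report = report)
}

channel_veog_correlation <- function(trial) {
  v <- trial$veog
  if (stats::sd(v) == 0) return(rep(NA_real_, nrow(trial$data)))
  apply(trial$data, 1, function(ch) {
    if (stats::sd(ch) == 0) NA_real_ else stats::cor(ch, v)
  })
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf("wCCA denoise report: rho1 = %.4f, energy removed u1 = %.1f%%, v1 = %.1f%%\n",
              x$rho1, 100 * x$energy_removed["u1"],
              100 * x$energy_removed["v1"]))
  cat(sprintf("  mean |VEOG corr| pre = %.3f, post = %.3f\n",
              mean(abs(x$veog_correlation$pre), na.rm = TRUE),
              mean(abs(x$veog_correlation$post), na.rm = TRUE)))
  invisible(x)
}

#' Wavelet threshold denoising of the midline channels
#'
#' The midline electrodes FZ and CZ have no mirrored partner, so the
#' cross-hemisphere canonical decomposition does not apply; they are
#' cleaned channel-wise by soft wavelet threshold denoising instead.
#'
#' @param trial an [eeg_trial()] containing the montage's central
#'   channels.
#' @param montage the [montage()].
#' @param spec a [wavelet_spec()]; the rule is forced to "soft" and the
#'   scope to "details" (classic denoising never shrinks the
#'   approximation band, which carries the signal baseline).
#' @return The trial with its central channels denoised.
#' @export
wtd_central <- function(trial, montage = default_montage(),
                        spec = wavelet_spec()) {
  if (!all(montage$central_group %in% rownames(trial$data)))
    stop("trial lacks central channels: ",
         paste(setdiff(montage$central_group, rownames(trial$data)),
               collapse = ", "))
  spec$threshold_rule <- "soft"
  spec$threshold_scope <- "details"
  out <- trial
  for (ch in montage$central_group)
    out$data[ch, ] <- wavelet_denoise(trial$data[ch, ], spec)
  out
}

#' Full per-trial preprocessing chain
#'
#' Temporal filtering (optional notch, band-pass), cropping to the
#' motor-imagery window, wCCA cleaning of the symmetric channels and soft
#' wavelet denoising of the midline channels.
#'
#' @param trial a raw [eeg_trial()] (full trial length).
#' @param montage the [montage()].
#' @param fspec a [filter_spec()].
#' @param wspec a [wavelet_spec()].
#' @param window analysis window in seconds relative to trial onset;
#'   `NULL` keeps the full trial.
#' @param notch apply the notch stage?
#' @param wcca apply the wCCA stage (disable for ablation)?
#' @return Preprocessed `eeg_trial`.
#' @export
preprocess_trial <- function(trial, montage = default_montage(),
                             fspec = filter_spec(),
                             wspec = wavelet_spec(),
                             window = c(2, 7), notch = TRUE, wcca = TRUE) {
  out <- filter_trial(trial, fspec, notch = notch)
  if (!is.null(window)) out <- crop_trial(out, window)
  if (wcca) {
    out <- wcca_denoise(out, montage, wspec)$trial
    out <- wtd_central(out, montage, wspec)
  }
  out
}

#' Preprocess every trial of a dataset
#'
#' @param dataset an [eeg_dataset()].
#' @inheritParams preprocess_trial
#' @return The dataset with preprocessed trials.
#' @export
preprocess_dataset <- function(dataset, montage = default_montage(),
                               fspec = filter_spec(),
                               wspec = wavelet_spec(),
                               window = c(2, 7), notch = TRUE, wcca = TRUE) {
  dataset$trials <- lapply(dataset$trials, preprocess_trial,
                           montage = montage, fspec = fspec,
                           wspec = wspec, window = window,
                           notch = notch, wcca = wcca)
  dataset
}

#' Per-trial wCCA diagnostics for a dataset
#'
#' Applies [wcca_denoise()] to every trial and tabulates the first
#' canonical correlation, the energy removed from the first canonical
#' pair and the mean absolute VEOG correlation of the frontal channels
#' before and after cleaning. Suitable for writing as a delimited report.
#'
#' @param dataset an [eeg_dataset()].
#' @param montage the [montage()].
#' @param spec a [wavelet_spec()].
#' @param frontal channels summarized in the VEOG-correlation columns.
#' @return data.frame with one row per trial.
#' @export
wcca_report_table <- function(dataset, montage = default_montage(),
                              spec = wavelet_spec(),
                              frontal = c("FC3", "FC4")) {
  rows <- lapply(seq_along(dataset$trials), function(i) {
    rep <- wcca_denoise(dataset$trials[[i]], montage, spec)$report
    vc <- rep$veog_correlation
    fr <- vc$channel %in% frontal
    data.frame(trial = i, label = dataset$trials[[i]]$label,
               rho1 = rep$rho1,
               energy_removed_u1 = unname(rep$energy_removed["u1"]),
               energy_removed_v1 = unname(rep$energy_removed["v1"]),
               frontal_veog_corr_pre = mean(abs(vc$pre[fr])),
               frontal_veog_corr_post = mean(abs(vc$post[fr])))
  })
  do.call(rbind, rows)
}
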