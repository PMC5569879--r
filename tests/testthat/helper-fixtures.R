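# Shared fixtures, built in code at test time.

tiny_config <- function(seed = 1, trials_per_state = 6,
                        train_per_state = 4, ...) {
  synthetic_config(n_subjects = 1, trials_per_state = trials_per_state,
                   train_per_state = train_per_state, seed = seed, ...)
}

# Four well-separated Gaussian clouds in 2-D feature space.
separable_clouds <- function(n_per_class, sd = 1, sep = 6, seed = 1) {
  set.seed(seed)
  mu <- list(R = c(0, 0), RF = c(sep, 0), LH = c(0, sep), RS = c(sep, sep))
  x <- NULL; y <- NULL
  for (cl in class_levels()) {
    x <- rbind(x, sweep(matrix(rnorm(n_per_class * 2, sd = sd),
                               n_per_class), 2, mu[[cl]], "+"))
    y <- c(y, rep(cl, n_per_class))
  }
  list(x = x, y = y)
}

# A hand-built trial with known channel content.
flat_trial <- function(n = 256, fs = 256, label = "R") {
  m <- default_montage()
  data <- matrix(0, length(m$eeg_channels), n,
                 dimnames = list(m$eeg_channels, NULL))
  eeg_trial(data + stats::rnorm(length(data), sd = 1), stats::rnorm(n),
            label, fs)
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
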