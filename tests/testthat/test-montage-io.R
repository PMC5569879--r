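test_that("montage validation enforces the partition and mirror pairing", {
  m <- default_montage()
  expect_length(m$eeg_channels, 14)
  expect_length(m$left_group, 6)
  expect_length(m$right_group, 6)
  expect_setequal(c(m$left_group, m$right_group, m$central_group),
                  m$eeg_channels)
  expect_error(montage(c("A", "B"), "A", "B", character(0), "A", 256),
               "outside eeg_channels")
  expect_error(montage(c("A", "B", "C"), c("A", "B"), "C", character(0),
                       "V", 256), "equal length")
  expect_error(montage(c("A", "B"), "A", "B", "B", "V", 256), "overlap")
  expect_error(montage(c("A", "B"), "A", "B", character(0), "V", -1),
               "fs must be positive")
})

test_that("delimited round trip preserves data and events", {
  set.seed(5)
  m <- default_montage()
  data <- matrix(rnorm(15 * 600), 15,
                 dimnames = list(c(m$eeg_channels, "VEOG"), NULL))
  rec <- eeg_recording(data, m,
                       data.frame(onset_sample = c(0L, 256L),
                                  label = c("LH", "RS")))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- load_recording(path, "delimited", m)
  expect_matrix_equal(back$data, rec$data, tol = 1e-9)
  expect_equal(back$events$onset_sample, rec$events$onset_sample,
               ignore_attr = TRUE)
  expect_identical(back$events$label, rec$events$label)
})

test_that("channels are reordered to montage order; missing channels error", {
  set.seed(6)
  m <- default_montage()
  chans <- c(m$eeg_channels, "VEOG")
  data <- matrix(rnorm(15 * 100), 15, dimnames = list(chans, NULL))
  rec <- eeg_recording(data, m, data.frame(onset_sample = 0L, label = "R"))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  # shuffle the columns of the file (channels) and lower-case the header
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  perm <- sample(ncol(df))
  df <- df[, perm]
  names(df) <- tolower(names(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- load_recording(path, "delimited", m)
  expect_matrix_equal(back$data, data, tol = 1e-9)

  df$c3 <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_recording(path, "delimited", m), "montage mismatch.*C3")
})

test_that("epoching cuts half-open windows and splits out VEOG", {
  m <- default_montage()
  n <- 9 * 256
  data <- matrix(rnorm(15 * n), 15,
                 dimnames = list(c(m$eeg_channels, "VEOG"), NULL))
  rec <- eeg_recording(data, m, data.frame(onset_sample = 0L, label = "LH"))
  trials <- epoch_trials(rec, c(2, 7))
  expect_length(trials, 1)
  expect_equal(ncol(trials[[1]]$data), 1280)  # 5 s x 256 Hz
  expect_equal(nrow(trials[[1]]$data), 14)
  expect_equal(trials[[1]]$label, "LH")
  # onset sample included, end excluded, 0-based indexing
  expect_equal(trials[[1]]$data["C3", 1], data["C3", 2 * 256 + 1])
  expect_equal(trials[[1]]$veog, unname(data["VEOG", (2 * 256 + 1):(7 * 256)]))
  expect_error(epoch_trials(rec, c(0, 0)), "end > start")
})

test_that("events running past the record end are reported as truncated", {
  m <- default_montage()
  n <- 20 * 256
  data <- matrix(rnorm(15 * n), 15,
                 dimnames = list(c(m$eeg_channels, "VEOG"), NULL))
  ev <- data.frame(onset_sample = c(0L, 9L * 256L, n - 256L),
                   label = c("R", "RF", "LH"))
  rec <- eeg_recording(data, m, ev)
  expect_warning(trials <- epoch_trials(rec, c(2, 7)), "truncated epoch")
  expect_length(trials, 2)
  expect_identical(vapply(trials, function(t) t$label, ""), c("R", "RF"))
})

test_that("epoched windows never exceed the source and keep labels", {
  set.seed(8)
  cfg <- tiny_config()
  ds <- generate_dataset(cfg)[[1]]
  rec <- dataset_to_recording(ds)
  trials <- epoch_trials(rec, c(0, 9))
  expect_length(trials, length(ds$trials))
  expect_identical(vapply(trials, function(t) t$label, ""),
                   dataset_labels(ds))
  expect_lte(length(trials) * ncol(trials[[1]]$data), ncol(rec$data))
  expect_matrix_equal(trials[[3]]$data, ds$trials[[3]]$data, 1e-12)
})

test_that("EDF round trip recovers microvolt data and handles mV scaling", {
  set.seed(9)
  m <- default_montage()
  data <- matrix(rnorm(15 * 512, sd = 30), 15,
                 dimnames = list(c(m$eeg_channels, "VEOG"), NULL))
  rec <- eeg_recording(data, m, data.frame(onset_sample = 0L, label = "RS"))
  path <- tempfile(fileext = ".edf")
  mibci:::write_edf(rec, path)
  back <- load_recording(path, "edf", m)
  # 16-bit quantization bounds the round-trip error
  expect_matrix_equal(back$data, data, tol = 0.05)
  expect_identical(back$events$label, "RS")

  mibci:::write_edf(rec, path, phys_dim = "mV")
  back_mv <- read_edf(path, m)
  expect_matrix_equal(back_mv$data, data, tol = 5)
  expect_error(load_recording(tempfile(), "delimited", m), "cannot read")
})

test_that("crop_trial validates windows", {
  tr <- flat_trial(n = 2304, fs = 256)
  expect_equal(ncol(crop_trial(tr, c(2, 7))$data), 1280)
  expect_error(crop_trial(tr, c(5, 5)), "end > start")
  expect_error(crop_trial(tr, c(8, 10)), "outside the trial")
})
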