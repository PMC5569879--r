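# Minimal European Data Format (EDF) support: continuous recordings with
# identical per-signal sampling rates, 16-bit samples, physical dimension
# microvolt or millivolt. Covers the ingestion needs of this pipeline; it
# is not a general EDF(+) implementation (no annotations, no
# discontinuous records).

read_edf_header <- function(con) {
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_records <- as.integer(rd(8)); record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); transducer <- fld(80); dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80); n_samples <- as.integer(fld(8)); fld(32)
  list(n_records = n_records, record_dur = record_dur, ns = ns,
       labels = labels, dim = dim, phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samples = n_samples)
}

#' Read a continuous EDF recording
#'
#' Reads a plain EDF file, converts each signal to microvolts (accepting
#' physical dimensions uV and mV) and resolves channel labels against the
#' montage case-insensitively. Events, which EDF proper does not carry,
#' are read from a sidecar `<stem>_events.tsv` when present (columns
#' `onset_s`, `label`).
#'
#' @param path path to the `.edf` file.
#' @param montage the [montage()] to resolve channels against.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, montage = default_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  total <- h$n_records * sum(h$n_samples)
  digital <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                     endian = "little")
  sigs <- vector("list", h$ns)
  for (i in seq_len(h$ns)) sigs[[i]] <- numeric(h$n_records * h$n_samples[i])
  pos <- 0L
  for (r in seq_len(h$n_records)) {
    for (i in seq_len(h$ns)) {
      ni <- h$n_samples[i]
      sigs[[i]][((r - 1L) * ni + 1L):(r * ni)] <- digital[(pos + 1L):(pos + ni)]
      pos <- pos + ni
    }
  }
  scale_to_uv <- vapply(h$dim, function(d) {
    d <- tolower(gsub("µ", "u", d))
    if (d %in% c("uv", "")) 1
    else if (d == "mv") 1000
    else stop("unsupported EDF physical dimension: ", d)
  }, numeric(1))
  mat <- matrix(0, nrow = h$ns, ncol = h$n_records * h$n_samples[1])
  for (i in seq_len(h$ns)) {
    gain <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    phys <- (sigs[[i]] - h$dig_min[i]) * gain + h$phys_min[i]
    mat[i, ] <- phys * scale_to_uv[i]
  }
  rownames(mat) <- h$labels
  fs <- h$n_samples[1] / h$record_dur
  if (abs(fs - montage$fs) > 1e-9)
    stop("EDF sampling rate ", fs, " Hz does not match montage fs ",
         montage$fs, " Hz")
  mat <- match_montage_rows(mat, montage)
  evp <- events_path(path)
  events <- data.frame(onset_sample = integer(0), label = character(0))
  if (file.exists(evp)) {
    ev <- utils::read.table(evp, header = TRUE, sep = "\t")
    events <- data.frame(onset_sample = round(ev$onset_s * montage$fs),
                         label = as.character(ev$label))
  }
  eeg_recording(mat, montage, events)
}

# Internal EDF writer used to exercise the reader in tests and to export
# synthetic recordings. One data record per second.
write_edf <- function(recording, path, phys_dim = "uV") {
  m <- recording$montage
  fs <- m$fs
  data <- recording$data
  if (tolower(phys_dim) == "mv") data <- data / 1000
  ns <- nrow(data)
  n_records <- floor(ncol(data) / fs)
  data <- data[, seq_len(n_records * fs), drop = FALSE]
  pmin <- floor(min(data)) - 1
  pmax <- ceiling(max(data)) + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf("%-*s", w, as.character(x))
    writeBin(charToRaw(substr(s, 1, w)), con)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * (ns + 1), 8); pad("", 44)
  pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (lab in rownames(data)) pad(lab, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(phys_dim, 8)
  for (i in seq_len(ns)) pad(pmin, 8)
  for (i in seq_len(ns)) pad(pmax, 8)
  for (i in seq_len(ns)) pad(dmin, 8)
  for (i in seq_len(ns)) pad(dmax, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(fs, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((data[i, idx] - pmin) / gain + dmin)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  ev <- data.frame(onset_s = recording$events$onset_sample / fs,
                   label = recording$events$label)
  utils::write.table(ev, events_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
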