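# Minimal EDF (European Data Format) writer/reader for continuous EEG.
# EDF is the ubiquitous EEG interchange format: a 256-byte ASCII header,
# 256 bytes per signal, then 1-second data records of little-endian int16
# samples scaled channel-wise between physical and digital extrema. Only the
# subset needed for continuous uV recordings is implemented; files written
# here are readable by standard tools (verified against Python MNE in the
# test suite).

.edf_fix <- function(s, w) {
  s <- substr(as.character(s), 1, w)
  sprintf(paste0("%-", w, "s"), s)
}

#' Write a continuous recording to EDF
#'
#' Samples are quantised to 16 bits over each channel's physical range, so the
#' round-trip error is bounded by range / 65534. The final partial data record
#' is zero-padded to a whole one-second record (EDF has no partial records);
#' the padding sits after the last epoch-bearing sample and is harmless to
#' the downstream analysis.
#'
#' @param recording A `ContinuousRecording`.
#' @param path Output file path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  X <- recording$samples
  fs <- recording$sampling_rate
  stopifnot(fs == round(fs))
  nch <- nrow(X)
  spr <- as.integer(fs)                      # one-second records
  nrec <- as.integer(ceiling(ncol(X) / spr))
  pad <- nrec * spr - ncol(X)
  if (pad > 0) X <- cbind(X, matrix(0, nch, pad))
  pmin <- floor(apply(X, 1, min))
  pmax <- ceiling(apply(X, 1, max))
  pmax <- pmax(pmax, pmin + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .edf_fix("0", 8), .edf_fix("X X X X", 80),
    .edf_fix("Startdate 01-JAN-2024 X X X", 80),
    .edf_fix("01.01.24", 8), .edf_fix("00.00.00", 8),
    .edf_fix(256 * (nch + 1), 8), .edf_fix("", 44),
    .edf_fix(nrec, 8), .edf_fix("1", 8), .edf_fix(nch, 4)),
    con, eos = NULL)
  wfield <- function(vals, w) {
    writeChar(paste0(vapply(vals, .edf_fix, "", w = w), collapse = ""),
              con, eos = NULL)
  }
  wfield(recording$channels, 16)
  wfield(rep("", nch), 80)
  wfield(rep("uV", nch), 8)
  wfield(format(pmin, trim = TRUE, scientific = FALSE), 8)
  wfield(format(pmax, trim = TRUE, scientific = FALSE), 8)
  wfield(rep("-32768", nch), 8)
  wfield(rep("32767", nch), 8)
  wfield(rep("", nch), 80)
  wfield(rep(spr, nch), 8)
  wfield(rep("", nch), 32)
  scale <- 65535 / (pmax - pmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((X[, cols, drop = FALSE] - pmin) * scale - 32768)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `samples` (channels x timepoints matrix, physical units),
#'   `sampling_rate`, `channels`, `physical_dimension`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rfield <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rfield(8); rfield(80); rfield(80); rfield(8); rfield(8)
  rfield(8); rfield(44)
  nrec <- as.integer(rfield(8))
  recdur <- as.numeric(rfield(8))
  nch <- as.integer(rfield(4))
  if (is.na(nch) || nch < 1) stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(nch), function(i) rfield(16), "")
  vapply(seq_len(nch), function(i) rfield(80), "")
  dims <- vapply(seq_len(nch), function(i) rfield(8), "")
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rfield(8), ""))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rfield(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rfield(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rfield(8), ""))
  vapply(seq_len(nch), function(i) rfield(80), "")
  spr <- as.integer(vapply(seq_len(nch), function(i) rfield(8), ""))
  vapply(seq_len(nch), function(i) rfield(32), "")
  if (length(unique(spr)) != 1) {
    stop("mixed per-signal sampling rates are not supported")
  }
  X <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, integer(), n = nch * spr[1], size = 2,
                   endian = "little")
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    X[, cols] <- matrix(raw, nrow = nch, byrow = TRUE)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  X <- (X - dmin) * scale + pmin
  fs <- spr[1] / recdur
  list(samples = X, sampling_rate = fs, channels = labels,
       physical_dimension = dims)
}

#' Write an event table as CSV
#'
#' Columns `sample_index` (0-based, for interchange with common EEG tooling)
#' and `event_code`. The in-memory representation is 1-based.
#'
#' @param events Data frame with `sample` (1-based) and `code`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(
    data.frame(sample_index = events$sample - 1L, event_code = events$code),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table CSV
#'
#' @param path CSV path with columns `sample_index` (0-based), `event_code`.
#' @param n_samples Optional recording length for range validation.
#' @return Data frame with `sample` (1-based) and `code`.
#' @export
read_events <- function(path, n_samples = NULL) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(sample = as.integer(ev$sample_index) + 1L,
                    code = as.character(ev$event_code),
                    stringsAsFactors = FALSE)
  if (nrow(out) && !is.null(n_samples) && any(out$sample > n_samples)) {
    bad <- which(out$sample > n_samples)[1]
    stop(sprintf("event row %d at sample %d is beyond the recording (%d)",
                 bad, out$sample[bad], n_samples))
  }
  if (nrow(out) > 1 && any(diff(out$sample) <= 0)) {
    stop("event sample indices must be strictly increasing")
  }
  out
}

#' Write a recording as EDF plus event CSV
#'
#' @param recording A `ContinuousRecording`.
#' @param base Path prefix; writes `<base>.edf` and `<base>_events.csv`.
#' @return `base`, invisibly.
#' @export
write_recording <- function(recording, base) {
  write_edf(recording, paste0(base, ".edf"))
  write_events(recording$events, paste0(base, "_events.csv"))
  invisible(base)
}

#' Read a recording from EDF plus event CSV
#'
#' Samples are converted to uV: the EDF physical-dimension field must read
#' "uV" (or "mV", converted on load). Channel labels are validated against
#' the expected montage; unknown labels are kept with a warning.
#'
#' @param base Path prefix as written by [write_recording()].
#' @param montage Expected channel labels (default [dry_montage()]).
#' @return A `ContinuousRecording`.
#' @export
read_recording <- function(base, montage = dry_montage()) {
  edf <- read_edf(paste0(base, ".edf"))
  for (i in seq_along(edf$channels)) {
    if (identical(edf$physical_dimension[i], "mV")) {
      edf$samples[i, ] <- edf$samples[i, ] * 1000
    } else if (!identical(edf$physical_dimension[i], "uV")) {
      warning("channel ", edf$channels[i], " has physical dimension '",
              edf$physical_dimension[i], "', assuming uV")
    }
  }
  unknown <- setdiff(edf$channels, montage)
  if (length(unknown)) {
    warning("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  events <- read_events(paste0(base, "_events.csv"), ncol(edf$samples))
  structure(list(samples = edf$samples, sampling_rate = edf$sampling_rate,
                 channels = edf$channels, events = events),
            class = "ContinuousRecording")
}

#' Write / read the session manifest
#'
#' @param manifest Data frame with participant, session, date, task,
#'   attempted, complete.
#' @param path JSON path.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$date <- as.character(m$date)
  jsonlite::write_json(m, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  m$date <- as.Date(m$date)
  m
}
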