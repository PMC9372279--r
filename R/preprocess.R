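#' Zero-phase band-pass filter
#'
#' Per-channel 4th-order Butterworth band-pass (default 0.25-40 Hz) applied
#' forward-backward with [signal::filtfilt()], so the effective magnitude
#' response is the squared Butterworth response and the phase response is
#' zero: ERP latencies are preserved, which the downstream SME score windows
#' depend on. Output length equals input length; events are unchanged.
#'
#' @param recording A `ContinuousRecording`.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return The filtered `ContinuousRecording`.
#' @export
bandpass_filter <- function(recording, low = 0.25, high = 40) {
  fs <- recording$sampling_rate
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("band must satisfy 0 < low < high < sampling_rate/2")
  }
  if (!all(is.finite(recording$samples))) {
    stop("recording contains non-finite samples")
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  for (ch in seq_len(nrow(out$samples))) {
    out$samples[ch, ] <- signal::filtfilt(bf, out$samples[ch, ])
  }
  out
}

#' Extract event-locked epochs
#'
#' Cuts one epoch per event over the half-open window \[-500, 1000) ms (the
#' sample at t = 0 belongs to the epoch). Events whose window would exceed
#' the recording bounds are dropped with a warning rather than zero-padded,
#' since padding would corrupt the spectral rejection metrics. Condition
#' labels are carried from the event codes and epochs keep their ordinal
#' recording position, which the sequential SME aggregation relies on.
#'
#' @param recording A `ContinuousRecording` (typically filtered).
#' @param events Optional event table (`sample`, `code`); defaults to the
#'   recording's own events.
#' @param locking `"stimulus"` or `"response"` (metadata label).
#' @param window_ms Epoch window endpoints in ms.
#' @return An `EpochSet`: list with `data` (epochs x channels x timepoints,
#'   uV), `time_ms`, `channels`, `condition`, `locking`, `retained`
#'   (epochs x channels logical mask, initially all `TRUE`), `ordinal`,
#'   `participant`, `session`, `sampling_rate`.
#' @export
extract_epochs <- function(recording, events = NULL,
                           locking = c("stimulus", "response"),
                           window_ms = c(-500, 1000)) {
  locking <- match.arg(locking)
  events <- events %||% recording$events
  if (is.null(events) || nrow(events) == 0) stop("empty event table")
  fs <- recording$sampling_rate
  t_ms <- epoch_time_axis(fs, window_ms)
  pre <- -round(window_ms[1] * fs / 1000)
  nt <- length(t_ms)
  N <- ncol(recording$samples)
  first <- events$sample - pre
  last <- first + nt - 1
  ok <- first >= 1 & last <= N
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  keep <- which(ok)
  data <- array(0, c(length(keep), nrow(recording$samples), nt))
  for (i in seq_along(keep)) {
    data[i, , ] <- recording$samples[, first[keep[i]]:last[keep[i]]]
  }
  structure(list(
    data = data, time_ms = t_ms, channels = recording$channels,
    condition = events$code[keep], locking = locking,
    retained = matrix(TRUE, length(keep), nrow(recording$samples)),
    ordinal = seq_along(events$sample)[keep],
    participant = recording$participant %||% NA_integer_,
    session = recording$session %||% NA_integer_,
    sampling_rate = fs), class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  cat(sprintf(
    "<EpochSet> %d epochs x %d ch x %d samples (%s-locked), %.0f%% retained\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$locking,
    100 * mean(x$retained)))
  invisible(x)
}

#' Baseline-adjust epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window from
#' the whole epoch, so the baseline-window mean is zero afterwards. The
#' operation is idempotent.
#'
#' @param epochs An `EpochSet`.
#' @param baseline_ms Baseline window `c(start, end)` in ms, half-open;
#'   \[-100, 0) for stimulus-locked oddball epochs, \[-500, -400) for
#'   response-locked flanker epochs.
#' @return The adjusted `EpochSet`.
#' @export
baseline_adjust <- function(epochs, baseline_ms = c(-100, 0)) {
  sel <- epochs$time_ms >= baseline_ms[1] & epochs$time_ms < baseline_ms[2]
  if (!any(sel)) stop("baseline window outside the epoch span")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over timepoints
  epochs
}

#' Default baseline window for a task
#'
#' @param task `"oddball"` (stimulus-locked, \[-100, 0) ms) or `"flanker"`
#'   (response-locked, \[-500, -400) ms).
#' @return Numeric window `c(start, end)` in ms.
#' @export
default_baseline <- function(task = c("oddball", "flanker")) {
  if (match.arg(task) == "oddball") c(-100, 0) else c(-500, -400)
}

#' Write / read the epoch container
#'
#' Epochs are persisted as a raw little-endian float64 array file plus a JSON
#' sidecar carrying the dimensions, time axis, channel labels, condition
#' labels, retention mask and identifiers, and round-trip losslessly.
#'
#' @param epochs An `EpochSet`.
#' @param base Path prefix; writes `<base>.f64` and `<base>.json`.
#' @return `base` (write) or the `EpochSet` (read).
#' @export
write_epochs <- function(epochs, base) {
  con <- file(paste0(base, ".f64"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(epochs$data), time_ms = epochs$time_ms,
               channels = epochs$channels, condition = epochs$condition,
               locking = epochs$locking,
               retained = as.integer(epochs$retained),
               ordinal = epochs$ordinal, participant = epochs$participant,
               session = epochs$session, sampling_rate = epochs$sampling_rate)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(base) {
  meta <- jsonlite::fromJSON(paste0(base, ".json"))
  n <- prod(meta$dim)
  con <- file(paste0(base, ".f64"), "rb")
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  close(con)
  structure(list(
    data = array(x, meta$dim), time_ms = meta$time_ms,
    channels = meta$channels, condition = meta$condition,
    locking = meta$locking,
    retained = matrix(as.logical(meta$retained), meta$dim[1], meta$dim[2]),
    ordinal = meta$ordinal, participant = meta$participant,
    session = meta$session, sampling_rate = meta$sampling_rate),
    class = "EpochSet")
}
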