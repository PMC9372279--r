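#' Dry-EEG headset montage
#'
#' Ordered 10-10 electrode labels of the simulated dry-EEG headset, referenced
#' to the left mastoid. The hardware is described as a 16-channel system; the
#' published electrode list carries the fifteen scalp positions returned here,
#' and the montage used throughout this package is exactly that printed list.
#'
#' @return Character vector of channel labels, in acquisition order.
#' @export
#' @examples
#' dry_montage()
dry_montage <- function() {
  c("O1", "O2", "P3", "Pz", "P4", "Cz", "FT7", "FC3", "FCz", "FC4",
    "FT8", "Fz", "AF7", "AF8", "FPz")
}

# Per-component channel gain maps. Values are relative gains applied to a
# component's peak amplitude. The common (visual/motor) maps are deliberately
# broad (floor ~0.85): the generator's default regime keeps event-locked
# signal on every channel and condition so that the correlation, Hurst and
# spectral-peak rejection stages separate clean epochs from contaminated ones
# (see the methods vignette for what this implies about real dry EEG).
.gain_map <- function(values) {
  stopifnot(all(names(values) %in% dry_montage()))
  g <- stats::setNames(rep(NA_real_, length(dry_montage())), dry_montage())
  g[names(values)] <- values
  stopifnot(!anyNA(g))
  g
}

.gains <- function() {
  list(
    # broad visual-evoked / readiness topography, posterior-weighted
    visual = .gain_map(c(
      O1 = 1, O2 = 1, P3 = 1, Pz = 1, P4 = 1, Cz = 0.95,
      FT7 = 0.9, FC3 = 0.9, FCz = 0.9, FC4 = 0.9, FT8 = 0.9, Fz = 0.9,
      AF7 = 0.85, AF8 = 0.85, FPz = 0.85)),
    # P300: centro-parietal, maximal at Pz
    p300 = .gain_map(c(
      O1 = 0.7, O2 = 0.7, P3 = 0.9, Pz = 1, P4 = 0.9, Cz = 0.8,
      FT7 = 0.45, FC3 = 0.5, FCz = 0.6, FC4 = 0.5, FT8 = 0.45, Fz = 0.5,
      AF7 = 0.4, AF8 = 0.4, FPz = 0.4)),
    # response-locked motor readiness, fronto-central but broad
    motor = .gain_map(c(
      O1 = 0.85, O2 = 0.85, P3 = 0.9, Pz = 0.9, P4 = 0.9, Cz = 0.95,
      FT7 = 0.9, FC3 = 0.95, FCz = 1, FC4 = 0.95, FT8 = 0.9, Fz = 0.95,
      AF7 = 0.9, AF8 = 0.9, FPz = 0.9)),
    # ERN / correct positivity: fronto-central, maximal at FCz
    fcz = .gain_map(c(
      O1 = 0.5, O2 = 0.5, P3 = 0.55, Pz = 0.6, P4 = 0.55, Cz = 0.85,
      FT7 = 0.7, FC3 = 0.9, FCz = 1, FC4 = 0.9, FT8 = 0.7, Fz = 0.85,
      AF7 = 0.6, AF8 = 0.6, FPz = 0.6)),
    # error positivity (Pe): posterior
    pe = .gain_map(c(
      O1 = 0.8, O2 = 0.8, P3 = 0.9, Pz = 1, P4 = 0.9, Cz = 0.8,
      FT7 = 0.5, FC3 = 0.55, FCz = 0.6, FC4 = 0.55, FT8 = 0.5, Fz = 0.55,
      AF7 = 0.45, AF8 = 0.45, FPz = 0.45)),
    # blink artifact: frontal-dominant (only these channels are contaminated)
    blink = c(AF7 = 1, AF8 = 1, FPz = 0.9, Fz = 0.6)
  )
}

# Gaussian-windowed ERP component evaluated on a time axis (seconds).
.gauss_comp <- function(t, amp, center, width) {
  amp * exp(-((t - center)^2) / (2 * width^2))
}

#' ERP template for one trial
#'
#' Builds the deterministic multi-channel ERP waveform injected by the
#' simulator for one epoch. Templates are sums of Gaussian-windowed components
#' with per-channel gain maps: stimulus-locked trials carry a readiness
#' negativity, P1, P2 and N2 on a broad visual topography, with targets adding
#' a P300 peaking at `p300_latency_ms` and maximal at Pz; response-locked
#' trials carry a motor readiness component, with correct responses adding a
#' fronto-central correct positivity (0-50 ms) and errors adding an ERN
#' (50-100 ms, maximal at FCz) followed by a posterior Pe.
#'
#' @param condition One of `"target"`, `"nontarget"`, `"correct"`, `"error"`.
#' @param config A [make_cohort_config()] configuration.
#' @param amp_factor Multiplicative amplitude factor for all components.
#' @param latency_shift_s Additive latency shift (seconds) applied to the
#'   condition-defining late component (P300, correct positivity, or ERN/Pe).
#' @return Matrix `channels x timepoints` (uV) over the epoch span
#'   \[-500, 1000) ms at the configured sampling rate.
#' @export
erp_template <- function(condition, config, amp_factor = 1,
                         latency_shift_s = 0) {
  fs <- config$sampling_rate
  t <- epoch_time_axis(fs) / 1000
  g <- .gains()
  nch <- length(config$montage)
  out <- matrix(0, nch, length(t), dimnames = list(config$montage, NULL))
  add <- function(gain, amp, center, width) {
    out + gain %o% .gauss_comp(t, amp, center, width)
  }
  if (condition %in% c("target", "nontarget")) {
    out <- add(g$visual, -4, -0.10, 0.08)   # readiness negativity
    out <- add(g$visual,  8,  0.12, 0.03)   # P1
    out <- add(g$visual,  9,  0.18, 0.035)  # P2
    out <- add(g$visual, -8,  0.25, 0.04)   # N2
    if (condition == "target") {
      out <- add(g$p300, config$p300_amplitude_uv,
                 config$p300_latency_ms / 1000 + latency_shift_s, 0.07)
    }
  } else if (condition %in% c("correct", "error")) {
    out <- add(g$motor, -12, -0.05, 0.06)   # motor readiness
    if (condition == "correct") {
      out <- add(g$fcz, config$correct_positivity_amplitude_uv,
                 mean(config$correct_positivity_window_ms) / 1000 +
                   latency_shift_s, 0.03)
    } else {
      out <- add(g$fcz, -config$ern_amplitude_uv,
                 mean(config$ern_window_ms) / 1000 + latency_shift_s, 0.03)
      out <- add(g$pe, 10, 0.25 + latency_shift_s, 0.08)
    }
  } else {
    stop("unknown condition: ", condition)
  }
  out * amp_factor
}

#' Epoch time axis
#'
#' Sample times of the standard epoch window, milliseconds relative to the
#' locking event. The window is half-open \[-500, 1000): the sample at t = 0
#' belongs to the epoch, the sample at +1000 ms does not, so an epoch holds
#' exactly 1.5 s x `fs` samples (375 at 250 Hz).
#'
#' @param fs Sampling rate in Hz.
#' @param window_ms Epoch window endpoints in ms (default `c(-500, 1000)`).
#' @return Numeric vector of sample times in ms.
#' @export
epoch_time_axis <- function(fs, window_ms = c(-500, 1000)) {
  i0 <- round(window_ms[1] * fs / 1000)
  i1 <- round(window_ms[2] * fs / 1000) - 1
  (i0:i1) / fs * 1000
}
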