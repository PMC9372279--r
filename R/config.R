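#' Cohort simulation configuration
#'
#' Builds the default simulation configuration for one study cohort. Defaults
#' mirror the structure of the at-home studies: oddball sessions present 30
#' target and 70 non-target stimuli across five blocks; flanker sessions
#' present 150 trials with errors drawn per trial at a 15% rate (mid-point of
#' the 10-20% band the adaptive gameplay targets); EEG is sampled at 250 Hz on
#' the dry montage; the P300 peaks ~350 ms post-stimulus at Pz in younger
#' adults and ~450 ms in older adults.
#'
#' Amplitudes, noise levels, inter-stimulus intervals and artifact prevalences
#' are not published for the raw dry recordings; their defaults are the
#' package's own documented choices (see the methods vignette) and are chosen
#' so that each artifact class is separable by a distinct rejection stage.
#'
#' @param cohort `"younger"` or `"older"`.
#' @param overrides Named list of fields to override. Unknown names are an
#'   error, and the merged configuration is re-validated.
#' @return A list of class `SimulationConfig`.
#' @export
#' @examples
#' cfg <- make_cohort_config("younger")
#' cfg$oddball_targets       # 30
#' cfg$p300_latency_ms       # 350
#' make_cohort_config("older")$p300_latency_ms  # 450
make_cohort_config <- function(cohort = c("younger", "older"),
                               overrides = list()) {
  cohort <- match.arg(cohort)
  cfg <- list(
    cohort = cohort,
    n_participants = if (cohort == "younger") 30L else 50L,
    n_sessions = if (cohort == "younger") 23L else 15L,
    sampling_rate = 250,
    montage = dry_montage(),
    oddball_targets = 30L,
    oddball_nontargets = 70L,
    flanker_trials = 150L,
    flanker_error_rate = 0.15,
    p300_latency_ms = if (cohort == "younger") 350 else 450,
    p300_amplitude_uv = 16,
    ern_amplitude_uv = 14,
    ern_window_ms = c(50, 100),
    correct_positivity_amplitude_uv = 10,
    correct_positivity_window_ms = c(0, 50),
    pink_sd_uv = 2.5,
    alpha_amplitude_uv = 0.8,
    blink_rate = 0.08,
    drift_rate = 0.05,
    burst_rate = 0.05,
    flatline_rate = 0.02,
    blink_amplitude_uv = 300,
    burst_amplitude_uv = 300,
    drift_excursion_uv = 1000,
    flatline_sd_uv = 0.3,
    participant_amp_jitter = 0.10,
    session_amp_jitter = 0.05,
    trial_amp_jitter = 0.15,
    participant_latency_jitter_ms = 10,
    trial_latency_jitter_ms = 8,
    isi_range_s = c(1.5, 3.0),
    incomplete_fraction = if (cohort == "younger") 0.04 else 0.07,
    seed = 1L
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be a named list")
    }
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

#' Validate a simulation configuration
#'
#' Checks the type invariants: positive counts, probabilities in \[0, 1\],
#' component latencies inside the epoch window, and an inter-stimulus-interval
#' floor no shorter than the epoch span (which guarantees non-overlapping
#' epochs).
#'
#' @param cfg A configuration list.
#' @return The configuration, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  counts <- c("n_participants", "n_sessions", "oddball_targets",
              "oddball_nontargets", "flanker_trials")
  for (f in counts) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 1 &&
          cfg[[f]] == round(cfg[[f]]), paste(f, "must be a positive count"))
  }
  probs <- c("flanker_error_rate", "blink_rate", "drift_rate", "burst_rate",
             "flatline_rate", "incomplete_fraction")
  for (f in probs) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste(f, "must be a probability in [0, 1]"))
  }
  chk(cfg$sampling_rate > 0, "sampling_rate must be positive")
  chk(is.character(cfg$montage) && length(cfg$montage) >= 1 &&
        !anyDuplicated(cfg$montage), "montage must be unique channel labels")
  chk(cfg$p300_latency_ms > -500 && cfg$p300_latency_ms < 1000,
      "p300_latency_ms must lie within the epoch window")
  chk(all(cfg$ern_window_ms > -500) && all(cfg$ern_window_ms < 1000),
      "ern_window_ms must lie within the epoch window")
  chk(cfg$pink_sd_uv >= 0 && cfg$alpha_amplitude_uv >= 0,
      "noise amplitudes must be non-negative")
  chk(length(cfg$isi_range_s) == 2 && cfg$isi_range_s[1] <= cfg$isi_range_s[2],
      "isi_range_s must be an increasing pair")
  chk(cfg$isi_range_s[1] >= 1.5,
      "isi_range_s floor must be >= 1.5 s so epochs cannot overlap")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be an integer")
  invisible(cfg)
}

# Deterministic master-seed -> child-seed derivation, keyed by
# (participant, session, task slot). Counter-based so that any (p, s, task)
# stream is reproducible in isolation; kept below 2^31 - 1.
child_seed <- function(master, participant, session = 0L, task = "") {
  tcode <- switch(task, oddball = 1L, flanker = 2L, manifest = 9L, 0L)
  as.integer((as.numeric(master) + 1000003 * participant + 10007 * session +
                101 * tcode) %% 2147483647)
}
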