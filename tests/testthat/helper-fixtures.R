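# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# small cohort config for fast end-to-end runs
small_config <- function(...) {
  make_cohort_config("younger", list(n_participants = 3L, n_sessions = 3L,
                                     seed = 42L, ...))
}

# a noiseless, artifact-free, jitter-free config: epochs equal the template
silent_config <- function(cohort = "younger") {
  make_cohort_config(cohort, list(
    n_participants = 2L, n_sessions = 2L, seed = 7L,
    pink_sd_uv = 0, alpha_amplitude_uv = 0,
    blink_rate = 0, drift_rate = 0, burst_rate = 0, flatline_rate = 0,
    participant_amp_jitter = 0, session_amp_jitter = 0, trial_amp_jitter = 0,
    participant_latency_jitter_ms = 0, trial_latency_jitter_ms = 0))
}

# one default-regime oddball session plus its processed result
processed_oddball <- function() {
  memo("processed_oddball", {
    cfg <- small_config()
    sim <- simulate_session(cfg, 1, 1, "oddball")
    pc <- pipeline_config(task = "oddball", cohort = "younger")
    list(sim = sim, config = cfg, pc = pc,
         ps = process_session(sim$recording, pc))
  })
}

# hand-built EpochSet from an epochs x timepoints matrix (single channel,
# one condition) for closed-form stage tests
toy_epochs <- function(mat, condition = rep("target", nrow(mat)),
                       channels = "Pz", fs = 250) {
  nt <- ncol(mat)
  data <- array(0, c(nrow(mat), length(channels), nt))
  for (ch in seq_along(channels)) data[, ch, ] <- mat
  structure(list(
    data = data, time_ms = epoch_time_axis(fs)[seq_len(nt)],
    channels = channels, condition = condition, locking = "stimulus",
    retained = matrix(TRUE, nrow(mat), length(channels)),
    ordinal = seq_len(nrow(mat)), participant = 1L, session = 1L,
    sampling_rate = fs), class = "EpochSet")
}

# independent straight-line Mann-Whitney enumeration oracle (bitmask walk,
# distinct from the combn-based implementation path)
mw_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  hits <- 0; total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[1:n])
    if (sum(bits) != na) next
    u <- sum(rk[bits == 1]) - na * (na + 1) / 2
    total <- total + 1
    if (u <= u_obs) hits <- hits + 1
  }
  list(U = u_obs, p = hits / total)
}
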