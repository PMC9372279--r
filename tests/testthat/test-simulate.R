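test_that("oddball sessions carry exactly the configured event counts", {
  sim <- processed_oddball()$sim
  ev <- sim$recording$events
  expect_equal(nrow(ev), 100)
  expect_equal(sum(ev$code == "target"), 30)
  expect_equal(sum(ev$code == "nontarget"), 70)
  expect_true(all(diff(ev$sample) > 0))
  expect_true(max(ev$sample) <= ncol(sim$recording$samples))
})

test_that("flanker correct + error always sum to the trial count", {
  cfg <- small_config()
  for (s in 1:3) {
    sim <- simulate_session(cfg, 1, s, "flanker")
    tab <- table(sim$recording$events$code)
    expect_equal(sum(tab[c("correct", "error")]), 150)
    expect_gt(tab[["error"]], 0)
  }
})

test_that("a fixed seed reproduces recordings bit-for-bit", {
  cfg <- small_config()
  a <- simulate_session(cfg, 2, 1, "oddball")
  b <- simulate_session(cfg, 2, 1, "oddball")
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$recording$events, b$recording$events)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_session(cfg, 2, 1, "oddball", seed = 99L)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("zero-noise target epochs equal the injected template exactly", {
  cfg <- silent_config()
  sim <- simulate_session(cfg, 1, 1, "oddball")
  ep <- extract_epochs(sim$recording, locking = "stimulus")
  tpl <- erp_template("target", cfg)
  pz <- match("Pz", cfg$montage)
  targets <- which(ep$condition == "target")
  for (i in targets[1:5]) {
    expect_equal(ep$data[i, pz, ], tpl[pz, ], tolerance = 1e-12)
  }
  # pointwise median across epochs recovers the template on every channel
  med <- median_erp(ep, "target")$target
  expect_equal(unname(med), unname(tpl), tolerance = 1e-12)
})

test_that("artifact flags follow the configured blink rate (binomial check)", {
  cfg <- make_cohort_config("younger", list(
    n_participants = 1L, n_sessions = 5L, seed = 11L,
    blink_rate = 0.2, drift_rate = 0, burst_rate = 0, flatline_rate = 0))
  flagged <- 0; total <- 0
  for (s in 1:5) {
    gt <- simulate_session(cfg, 1, s, "oddball")$ground_truth
    blink <- gt$artifact_types$type == "blink"
    flagged <- flagged + sum(blink)
    total <- total + length(gt$condition)
  }
  # 500 epochs at rate 0.2: 95% binomial interval ~ [0.165, 0.235]
  ci <- qbinom(c(0.0025, 0.9975), total, 0.2) / total
  expect_gte(flagged / total, ci[1])
  expect_lte(flagged / total, ci[2])
})

test_that("recorded background score SD matches the empirical score noise", {
  # score minus the known injected-template score isolates the background
  # contribution; its SD must match the closed-form value in the ground truth
  cfg <- make_cohort_config("younger", list(
    n_participants = 1L, n_sessions = 5L, seed = 5L,
    blink_rate = 0, drift_rate = 0, burst_rate = 0, flatline_rate = 0))
  resid <- numeric()
  nsd <- NA
  for (s in 1:5) {
    sim <- simulate_session(cfg, 1, s, "flanker")
    rec <- bandpass_filter(sim$recording)
    ep <- baseline_adjust(extract_epochs(rec, locking = "response"),
                          default_baseline("flanker"))
    sc <- window_scores(ep, score_window("flanker", "younger"), "correct")
    gt <- sim$ground_truth
    resid <- c(resid, sc$score - gt$template_score[sc$ordinal])
    nsd <- gt$noise_score_sd
  }
  expect_gt(length(resid), 500)
  expect_equal(sd(resid), nsd, tolerance = 0.10)
})

test_that("cohort manifests have one row per participant-session-task", {
  cfg <- make_cohort_config("younger", list(
    n_participants = 2L, n_sessions = 3L, seed = 3L,
    incomplete_fraction = 0))
  sim <- simulate_cohort(cfg, manifest_only = TRUE)
  expect_equal(nrow(sim$manifest), 2 * 3 * 2)
  expect_true(all(sim$manifest$complete))
  # determinism of the full cohort object
  cfg2 <- make_cohort_config("younger", list(n_participants = 2L,
                                             n_sessions = 2L, seed = 3L))
  a <- simulate_cohort(cfg2, tasks = "oddball")
  b <- simulate_cohort(cfg2, tasks = "oddball")
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$recordings, b$recordings)
})

test_that("incomplete-session marking matches the configured fraction", {
  cfg <- make_cohort_config("older", list(
    n_participants = 50L, n_sessions = 15L, seed = 21L,
    incomplete_fraction = 0.07))
  m <- simulate_cohort(cfg, manifest_only = TRUE)$manifest
  days <- unique(m[, c("participant", "session", "complete")])
  rate <- mean(days$complete)
  ci <- qbinom(c(0.0025, 0.9975), nrow(days), 0.93) / nrow(days)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("simulation errors on out-of-range participants and sessions", {
  cfg <- small_config()
  expect_error(simulate_session(cfg, 99, 1, "oddball"), "participant")
  expect_error(simulate_session(cfg, 1, 99, "oddball"), "session")
  expect_error(simulate_session(cfg, 1, 1, "nback"))
})
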