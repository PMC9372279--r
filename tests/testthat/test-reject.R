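test_that("amplitude stage uses a strict 100 uV threshold", {
  base <- sin((1:375) / 30)
  mat <- rbind(base * 10, base / max(abs(base)) * 150,
               base / max(abs(base)) * 100, base * 5)
  ep <- toy_epochs(mat)
  out <- reject_amplitude(ep, 100)
  expect_identical(as.vector(out$retained), c(TRUE, FALSE, TRUE, TRUE))
  expect_error(reject_amplitude(ep, -5), "positive")
})

test_that("correlation stage matches a straight-line per-epoch oracle", {
  set.seed(31)
  tpl <- 8 * sin((1:375) / 25)
  n_sig <- 40; n_noise <- 10
  mat <- rbind(
    t(replicate(n_sig, tpl + rnorm(375, 0, 3))),   # template + noise
    t(replicate(n_noise, rnorm(375, 0, 8))))       # pure noise
  ep <- toy_epochs(mat)
  out <- reject_low_correlation(ep, 0.25)
  # independent oracle: plain correlation of each row with the grand mean
  avg <- colMeans(mat)
  r <- apply(mat, 1, cor, y = avg)
  expect_identical(as.vector(out$retained), r >= 0.25)
  # populations separate: all template epochs kept, most noise epochs gone
  expect_true(all(out$retained[1:n_sig]))
  expect_gt(mean(!out$retained[(n_sig + 1):(n_sig + n_noise)]), 0.7)
})

test_that("correlation stage handles exact, negated and flat epochs", {
  tpl <- sin((1:375) / 25)
  mat <- rbind(tpl, tpl, tpl, tpl, -3 * tpl, rep(0, 375))
  ep <- toy_epochs(mat)
  out <- reject_low_correlation(ep, 0.25)
  expect_true(all(out$retained[1:4]))       # r = 1 against the average
  expect_false(out$retained[5])             # negated: r < 0
  expect_false(out$retained[6])             # zero variance counts as r = 0
})

test_that("z-score stages remove gross outliers but spare homogeneity", {
  # a single outlier among n epochs can reach |z| of at most (n-1)/sqrt(n),
  # so the z > 15 gate needs a few hundred epochs to fire; use 400
  set.seed(32)
  mat <- t(replicate(400, 5 * sin((1:375) / 25) + rnorm(375)))
  mat[7, ] <- 1000 * sin((1:375) / 25)       # variance ~ 5e5, spectrum clean
  ep <- toy_epochs(mat)
  m <- compute_epoch_metrics(ep)
  expect_gt(m$z_variance[7], 15)
  out <- zscore_staged_reject(m, ep)
  expect_false(out$epochs$retained[7])
  expect_true("z_gross" %in% out$removed$stage[out$removed$epoch == 7])
  # identical epochs: degenerate z-distributions remove nothing
  same <- toy_epochs(t(replicate(20, 5 * sin((1:375) / 25))))
  ms <- compute_epoch_metrics(same)
  outs <- zscore_staged_reject(ms, same)
  expect_true(all(outs$epochs$retained[ms$hurst >= 0.65 &
                                         ms$spectral_peak >= 0.1]))
  expect_true(all(!outs$removed$stage %in% c("z_gross", "z_final")))
})

test_that("white-noise epochs fall to the Hurst/spectral-peak stage", {
  set.seed(33)
  ep <- toy_epochs(t(replicate(200, rnorm(375))))
  m <- compute_epoch_metrics(ep)
  out <- zscore_staged_reject(m, ep)
  expect_gte(mean(!out$epochs$retained), 0.98)
  expect_gte(mean(out$removed$stage == "hurst_spectral"), 0.98)
})

test_that("pipeline conserves counts and never un-rejects", {
  ps <- processed_oddball()$ps
  rep <- ps$report
  expect_true(all(rep$n_in - rep$rej_amplitude - rep$rej_correlation -
                    rep$rej_z_gross - rep$rej_hurst_spectral -
                    rep$rej_z_final == rep$n_out))
  expect_true(all(rep[, grep("^rej_", names(rep))] >= 0))
  expect_identical(rep$survived, rep$n_out >= 1)
  # zero-noise session, identical epochs: nothing is rejected at any stage
  # (the degenerate z-distributions must not divide by zero)
  cfg <- silent_config()
  sim <- simulate_session(cfg, 1, 1, "oddball")
  ep <- baseline_adjust(extract_epochs(sim$recording, locking = "stimulus"),
                        c(-100, 0))
  clean <- run_rejection_pipeline(ep)
  expect_true(all(clean$epochs$retained))
  expect_true(all(clean$report$n_in == clean$report$n_out))
})

test_that("the staged pipeline is deterministic (regression on stage totals)", {
  ps1 <- processed_oddball()$ps
  cfg <- small_config()
  sim <- simulate_session(cfg, 1, 1, "oddball")
  pc <- pipeline_config(task = "oddball", cohort = "younger")
  ps2 <- process_session(sim$recording, pc)
  expect_identical(ps1$report, ps2$report)
  expect_identical(ps1$epochs$retained, ps2$epochs$retained)
})

test_that("percent discarded rises with the contamination rate", {
  pc <- pipeline_config(task = "oddball", cohort = "younger")
  discarded <- vapply(c(0, 0.1, 0.3), function(scale) {
    cfg <- make_cohort_config("younger", list(
      n_participants = 1L, n_sessions = 1L, seed = 17L,
      blink_rate = 0.4 * scale, drift_rate = 0.25 * scale,
      burst_rate = 0.25 * scale, flatline_rate = 0.1 * scale))
    sim <- simulate_session(cfg, 1, 1, "oddball")
    rep <- process_session(sim$recording, pc)$report
    1 - sum(rep$n_out) / sum(rep$n_in)
  }, 0)
  expect_true(all(diff(discarded) > 0))
})
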