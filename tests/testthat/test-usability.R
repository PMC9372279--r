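test_that("adherence summary counts attempts, completion and weeks", {
  m <- expand.grid(participant = 1:10, session = 1:20)
  m$date <- as.Date("2024-01-01") + (m$session - 1)
  m$task <- "oddball"
  m$attempted <- TRUE
  m$complete <- TRUE
  adh <- adherence_summary(m, requested = 20)
  expect_equal(adh$cohort$mean_attempted, 20)
  expect_equal(adh$cohort$mean_pct_complete, 100)
  expect_true(all(adh$per_participant$pct_complete >= 0 &
                    adh$per_participant$pct_complete <= 100))
  # rolling 7-day weeks from each participant's first session
  expect_equal(sort(unique(adh$weekly$week)), 1:3)
  expect_equal(adh$weekly$attempted[adh$weekly$week == 1 &
                                      adh$weekly$participant == 1], 7)
  # a participant attempting more than requested is reported, not clipped
  extra <- rbind(m, data.frame(participant = 1, session = 21:25,
                               date = as.Date("2024-01-21") + 0:4,
                               task = "oddball", attempted = TRUE,
                               complete = TRUE))
  adh2 <- adherence_summary(extra, requested = 20)
  expect_equal(adh2$per_participant$attempted[1], 25)
  expect_gt(adh2$per_participant$attempted[1],
            adh2$per_participant$requested[1])
  expect_error(adherence_summary(m, 0), "positive")
  expect_error(adherence_summary(m[0, ], 10), "empty")
})

test_that("cohort completion tracks the generator's incomplete fraction", {
  cfg <- make_cohort_config("older", list(
    n_participants = 40L, n_sessions = 25L, seed = 13L,
    incomplete_fraction = 0.07))
  m <- simulate_cohort(cfg, manifest_only = TRUE)$manifest
  adh <- adherence_summary(m[m$task == "oddball", ], requested = 25)
  days <- 40 * 25
  ci <- 100 * qbinom(c(0.0025, 0.9975), days, 0.93) / days
  expect_gte(adh$cohort$mean_pct_complete, ci[1])
  expect_lte(adh$cohort$mean_pct_complete, ci[2])
})

test_that("channel survival percentages follow the reports", {
  rep <- expand.grid(channel = c("Pz", "Cz"), session = 1:100)
  rep$task <- "oddball"
  rep$condition <- "target"
  rep$survived <- TRUE
  rep$survived[rep$channel == "Cz" & rep$session <= 16] <- FALSE
  surv <- channel_survival(rep)
  expect_equal(surv$pct_surviving[surv$channel == "Pz"], 100)
  expect_equal(surv$pct_surviving[surv$channel == "Cz"], 84)
  expect_equal(unique(surv$n_sessions), 100)
})

test_that("a channel-specific noise source depresses that channel's survival", {
  # continuous broadband noise on Cz only: its epochs fail the Hurst /
  # spectral-peak stage, so Cz sessions die while other channels survive
  pc <- pipeline_config(task = "oddball", cohort = "younger")
  reports <- list()
  for (s in 1:4) {
    cfg <- make_cohort_config("younger", list(
      n_participants = 1L, n_sessions = 4L, seed = 50L,
      blink_rate = 0, drift_rate = 0, burst_rate = 0, flatline_rate = 0))
    sim <- simulate_session(cfg, 1, s, "oddball")
    cz <- match("Cz", cfg$montage)
    sim$recording$samples[cz, ] <- sim$recording$samples[cz, ] +
      rnorm(ncol(sim$recording$samples), 0, 80)
    rep <- process_session(sim$recording, pc)$report
    rep$task <- "oddball"
    reports[[s]] <- rep
  }
  surv <- channel_survival(do.call(rbind, reports))
  tgt <- surv[surv$condition == "target", ]
  cz_rate <- tgt$pct_surviving[tgt$channel == "Cz"]
  expect_lt(cz_rate, median(tgt$pct_surviving[tgt$channel != "Cz"]))
})

test_that("SUS scoring matches Brooke's formula across the scale", {
  expect_equal(sus_score(rep(c(5, 1), 5)), 100)   # odd 5s, even 1s
  expect_equal(sus_score(rep(c(1, 5), 5)), 0)     # odd 1s, even 5s
  expect_equal(sus_score(rep(3, 10)), 50)
  set.seed(61)
  for (i in 1:200) {
    r <- sample(1:5, 10, replace = TRUE)
    s <- sus_score(r)
    expect_gte(s, 0); expect_lte(s, 100)
    expect_equal(s %% 2.5, 0)
  }
  expect_error(sus_score(rep(3, 9)), "10 item")
  expect_error(sus_score(c(rep(3, 9), 6)), "1-5")
})

test_that("exact Mann-Whitney path agrees with enumeration oracles", {
  res <- compare_sus(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.05)    # 1 / choose(6, 3)
  expect_identical(res$method, "exact")
  set.seed(62)
  for (i in 1:12) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- sample(1:6, na, replace = TRUE)      # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    got <- compare_sus(a, b, "less")
    oracle <- mw_enum_oracle(a, b)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p_value, oracle$p)
  }
  # no-ties exact case cross-checked against the standard implementation
  a <- c(10.2, 11.5, 9.8, 13.1); b <- c(12.4, 14.2, 15.0, 11.1, 13.8)
  got <- compare_sus(a, b, "less")
  ref <- wilcox.test(a, b, alternative = "less", exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value))
  expect_equal(got$U, unname(ref$statistic))
})

test_that("identical groups give no evidence and degenerate input p = 0.5", {
  same <- compare_sus(c(80, 85, 90), c(80, 85, 90), "less")
  expect_gte(same$p_value, 0.5)
  flat <- compare_sus(rep(75, 5), rep(75, 7), "less")
  expect_equal(flat$p_value, 0.5)
  expect_identical(flat$method, "degenerate")
  expect_error(compare_sus(numeric(), 1:3), "non-empty")
})

test_that("the normal path holds its type-I error at the study's sizes", {
  set.seed(63)
  reject <- replicate(1000, {
    a <- rnorm(32, 85, 10); b <- rnorm(18, 85, 10)
    compare_sus(a, b, "less")$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
  # greater is the mirror image of less
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(compare_sus(b, a, "greater")$p_value,
               compare_sus(a, b, "less")$p_value)
})
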