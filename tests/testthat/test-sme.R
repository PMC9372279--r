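test_that("SME equals the closed form sigma / sqrt(n)", {
  scores <- c(0, 20, 0, 20) / 2 + 5          # sd = 5.7735, but use exact form
  expect_equal(sme(scores, 4), sd(scores) / 2)
  # independent straight-line SD: sqrt(sum((x - mean)^2) / (n - 1))
  x <- c(3.2, -1.5, 7.8, 0.4, 2.2)
  byhand <- sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / sqrt(length(x))
  expect_equal(sme(x), byhand)
  expect_equal(sme(rep(4.2, 10)), 0)
  expect_error(sme(x, 1), "n >= 2")
  expect_error(sme(x, 99), "fewer")
})

test_that("scores with SD 10 and n = 4 give SME 5", {
  x <- c(-10, 10, -10, 10) / sqrt(4 / 3)     # sample SD exactly 10
  expect_equal(sd(x), 10)
  expect_equal(sme(x, 4), 5)
})

test_that("sme on a data frame follows session-then-ordinal order", {
  df <- data.frame(participant = 1,
                   session = c(2, 1, 1, 2), ordinal = c(1, 2, 1, 2),
                   score = c(30, 2, 1, 40))
  # aggregation order: s1o1=1, s1o2=2, s2o1=30, s2o2=40
  expect_equal(sme(df, 2), sd(c(1, 2)) / sqrt(2))
})

test_that("median ERP is robust where the mean is not", {
  ep <- toy_epochs(rbind(matrix(1, 1, 375), matrix(2, 1, 375),
                         matrix(100, 1, 375)))
  med <- median_erp(ep)$target
  expect_true(all(med == 2))
  # 101 clean epochs + one at +1000 uV: median barely moves, mean jumps
  set.seed(41)
  clean <- t(replicate(101, 5 * sin((1:375) / 25) + rnorm(375)))
  ep2 <- toy_epochs(rbind(clean, rep(1000, 375)))
  med2 <- median_erp(ep2)$target
  base <- apply(clean, 2, median)
  expect_lt(max(abs(med2 - base)), 1)                   # < noise SD
  shift <- mean(colMeans(rbind(clean, rep(1000, 375))) - colMeans(clean))
  expect_gt(shift, 9)                                   # mean shifts ~9.8 uV
  # zero retained epochs leave a channel unavailable
  ep2$retained[, 1] <- FALSE
  expect_true(all(is.na(median_erp(ep2)$target)))
})

test_that("window scores reduce to closed forms on constant and ramp epochs", {
  win <- list(channel = "Pz", window_ms = c(300, 400), baseline_ms = c(-100, 0),
              conditions = "target")
  const <- toy_epochs(matrix(5, 1, 375))
  expect_equal(window_scores(const, win)$score, 5)
  # linear ramp: the window mean equals the mean of the sampled grid values
  t_ms <- epoch_time_axis(250)
  ramp <- 10 * (t_ms - 300) / 100
  ep <- toy_epochs(matrix(ramp, 1, byrow = TRUE))
  sel <- t_ms >= 300 & t_ms < 400
  expect_equal(window_scores(ep, win)$score, mean(ramp[sel]))
  expect_error(window_scores(ep, list(channel = "Qz", window_ms = c(0, 1),
                                      conditions = "target")), "channel")
})

test_that("score windows follow cohort and task conventions", {
  expect_equal(score_window("oddball", "younger")$window_ms, c(300, 400))
  expect_equal(score_window("oddball", "older")$window_ms, c(400, 500))
  expect_equal(score_window("oddball", "younger")$channel, "Pz")
  expect_equal(score_window("flanker", "older")$channel, "FCz")
  expect_equal(score_window("flanker", "younger")$window_ms, c(0, 100))
})

test_that("group curve pools participants by availability", {
  a <- data.frame(participant = 1, session = 1, ordinal = 1:40,
                  score = rep(c(1, 3), 20))
  b <- data.frame(participant = 2, session = 1, ordinal = 1:60,
                  score = rep(c(2, 4), 30))
  cc <- data.frame(participant = 3, session = 1, ordinal = 1:80,
                   score = rep(c(0, 2), 40))
  curve <- group_sme_curve(list(a, b, cc))
  expect_equal(curve$n_participants[curve$n == 10], 3)
  expect_equal(curve$n_participants[curve$n == 70], 1)
  expect_true(all(diff(curve$n_participants) <= 0))
  expect_true(all(curve$sme > 0))
  expect_true(all(curve$ci >= 0, na.rm = TRUE))
  # identical participants: group equals individual, CI = 0
  curve2 <- group_sme_curve(list(a, a))
  expect_equal(curve2$sme[curve2$n == 40], sme(a, 40))
  expect_equal(curve2$ci[curve2$n == 40], 0)
  expect_error(group_sme_curve(list(a)), ">= 2")
})

test_that("group SME over i.i.d. scores decays with log-log slope -1/2", {
  set.seed(43)
  scores <- lapply(1:12, function(i) {
    data.frame(participant = i, session = 1, ordinal = 1:300,
               score = rnorm(300, 0, 8))
  })
  curve <- group_sme_curve(scores)
  fit <- lm(log(sme) ~ log(n), curve)
  expect_lt(abs(unname(coef(fit)[2]) - (-0.5)), 0.05)
})

test_that("trials-to-reference finds the first grid crossing", {
  curve <- data.frame(n = 2:200, sme = 10.4 / sqrt(2:200))
  expect_equal(trials_to_reference(curve, 1.83), 33)
  expect_equal(trials_to_reference(curve, 100), 2)     # already below at n = 2
  expect_true(is.na(trials_to_reference(curve, 0)))    # never reached
  expect_true(is.na(trials_to_reference(curve, 0.1)))  # below the curve floor
  expect_error(trials_to_reference(curve[0, ], 1), "empty")
})

test_that("sessions-needed reproduces the published projections", {
  expect_equal(sessions_needed(33, 40, 0.43), 2L)
  expect_equal(sessions_needed(467, 352.1, 0.593), 4L)
  expect_equal(sessions_needed(56, 42, 0.40), 3L)
  expect_equal(sessions_needed(31, 40, 0.642), 3L)
  # monotone in both demand and rejection severity
  expect_true(all(diff(vapply(c(10, 40, 80, 200), sessions_needed,
                              0L, presented_per_session = 40,
                              rejection_fraction = 0.4)) >= 0))
  expect_true(all(diff(vapply(c(0, 0.3, 0.6, 0.9), function(f)
    sessions_needed(50, 40, f), 0L)) >= 0))
  expect_error(sessions_needed(10, 40, 1), "rejection_fraction")
  expect_error(sessions_needed(0, 40, 0.5), "positive")
})

test_that("expected surviving trials reproduce the yield table", {
  expect_equal(expected_surviving_trials(30, 0.43), 17.1)
  expect_equal(expected_surviving_trials(30, 0.642), 10.74)
  expect_equal(expected_surviving_trials(100, 0), 100)
})

test_that("reference constants are internally consistent", {
  bench <- reference_benchmarks()
  expect_equal(bench$wet$sme_uv, c(1.83, 0.51, 1.68))
  expect_equal(bench$wet$trials_surviving, c(30.5, 337, 40.1))
  # published available-trial counts match collected x (1 - discard) to the
  # table's printed precision
  dy <- bench$dry_yield
  derived <- expected_surviving_trials(dy$trials_collected,
                                       dy$pct_discarded / 100)
  expect_equal(round(derived, 1), dy$trials_available, tolerance = 0.11)
})
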