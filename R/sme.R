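#' Median ERP waveform
#'
#' Pointwise median across retained epochs, per channel and condition. The
#' median is used rather than the mean as a robust measure of central
#' tendency: a single extreme epoch barely moves it.
#'
#' @param epochs An `EpochSet` (after rejection).
#' @param conditions Conditions to average (default: all present).
#' @return Named list (by condition) of channels x timepoints matrices;
#'   channels with zero retained epochs are rows of `NA` (unavailable).
#' @export
median_erp <- function(epochs, conditions = NULL) {
  conditions <- conditions %||% unique(epochs$condition)
  nt <- dim(epochs$data)[3]
  out <- lapply(conditions, function(cond) {
    m <- matrix(NA_real_, length(epochs$channels), nt,
                dimnames = list(epochs$channels, NULL))
    for (ch in seq_along(epochs$channels)) {
      rows <- which(epochs$condition == cond & epochs$retained[, ch])
      if (length(rows) == 0) next
      sub <- epochs$data[rows, ch, , drop = FALSE]
      dim(sub) <- c(length(rows), nt)
      m[ch, ] <- apply(sub, 2, stats::median)
    }
    m
  })
  stats::setNames(out, conditions)
}

#' Per-trial window-mean scores
#'
#' One score per retained epoch of the requested condition at the analysis
#' channel: the mean voltage over the score window (the baseline-window mean
#' is already zero after [baseline_adjust()]). Scores keep their recording
#' order (session, then within-session ordinal), which defines the sequential
#' aggregation: the SME at n trials always uses a participant's first n
#' available trials.
#'
#' @param epochs An `EpochSet` (baseline-adjusted, rejection applied).
#' @param window A [score_window()] list (channel, window_ms, conditions).
#' @param condition Condition to score (default: the window's first).
#' @return Data frame `participant`, `session`, `ordinal`, `score` (uV).
#' @export
window_scores <- function(epochs, window, condition = NULL) {
  condition <- condition %||% window$conditions[1]
  ch <- match(window$channel, epochs$channels)
  if (is.na(ch)) stop("channel ", window$channel, " not in this EpochSet")
  sel <- epochs$time_ms >= window$window_ms[1] &
    epochs$time_ms < window$window_ms[2]
  rows <- which(epochs$condition == condition & epochs$retained[, ch])
  if (length(rows) == 0) {
    return(data.frame(participant = integer(), session = integer(),
                      ordinal = integer(), score = numeric()))
  }
  sub <- epochs$data[rows, ch, sel, drop = FALSE]
  dim(sub) <- c(length(rows), sum(sel))
  data.frame(participant = epochs$participant, session = epochs$session,
             ordinal = epochs$ordinal[rows], score = rowMeans(sub))
}

#' Standardized Measurement Error
#'
#' SME for the first `n` scores in recording order: the sample standard
#' deviation (n - 1 denominator) of those scores divided by sqrt(n). This is
#' the standard error of the participant's ERP score estimated from n trials.
#'
#' @param scores Numeric vector of per-trial scores in aggregation order, or
#'   a data frame from [window_scores()] (ordered by session then ordinal).
#' @param n Number of trials to use (`>= 2`; defaults to all).
#' @return SME in uV.
#' @export
#' @examples
#' sme(c(0, 10, 0, 10) + 2)   # sd 5.774 / 2
sme <- function(scores, n = NULL) {
  if (is.data.frame(scores)) {
    scores <- scores$score[order(scores$session, scores$ordinal)]
  }
  n <- n %||% length(scores)
  if (n < 2) stop("SME needs n >= 2")
  if (length(scores) < n) stop("fewer than n scores available")
  stats::sd(scores[seq_len(n)]) / sqrt(n)
}

#' Group-level SME curve over aggregated trials
#'
#' For each trial count n on the grid, participants with at least n available
#' scores contribute their individual SME over their first n trials; the
#' group value is the arithmetic mean of those SMEs with a 95% confidence
#' half-width of 1.96 x SD / sqrt(N). N (participants remaining) is
#' non-increasing in n and is reported alongside, as aggregation over more
#' trials progressively excludes participants.
#'
#' @param score_list Named list of per-participant score data frames (from
#'   [window_scores()], rows in recording order) or numeric vectors.
#' @param n_grid Trial counts to evaluate (default: every integer from 2 to
#'   the maximum available; truncated where no participant reaches n).
#' @return Data frame of class `SMECurve`: `n`, `sme` (uV), `ci` (uV),
#'   `n_participants`.
#' @export
group_sme_curve <- function(score_list, n_grid = NULL) {
  if (length(score_list) < 2) stop("need >= 2 participants")
  vecs <- lapply(score_list, function(s) {
    if (is.data.frame(s)) s$score[order(s$session, s$ordinal)] else s
  })
  avail <- vapply(vecs, length, 0L)
  n_grid <- n_grid %||% seq(2L, max(avail))
  n_grid <- n_grid[n_grid <= max(avail)]
  rows <- lapply(n_grid, function(n) {
    smes <- vapply(vecs[avail >= n], function(v) sme(v, n), 0)
    data.frame(n = n, sme = mean(smes),
               ci = 1.96 * stats::sd(smes) / sqrt(length(smes)),
               n_participants = length(smes))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SMECurve", "data.frame")
  out
}

#' Trials needed to reach a reference SME
#'
#' Smallest trial count on the curve's grid whose group SME is at or below
#' the reference value.
#'
#' @param curve An `SMECurve` (or data frame with `n` and `sme`).
#' @param reference_sme Reference SME in uV (> 0).
#' @return Integer trial count, or `NA` ("not reached") if the curve never
#'   crosses the reference.
#' @export
trials_to_reference <- function(curve, reference_sme) {
  if (nrow(curve) == 0) stop("empty SME curve")
  if (reference_sme <= 0) return(NA_integer_)
  hit <- which(curve$sme <= reference_sme)
  if (length(hit) == 0) NA_integer_ else as.integer(curve$n[min(hit)])
}

#' Sessions needed to collect the required trials
#'
#' Projects how many at-home recording sessions are needed to accumulate
#' `n_required` post-rejection trials, given the number of trials presented
#' per session and the fraction lost to epoch rejection:
#' `ceiling(n_required / (presented_per_session * (1 - rejection_fraction)))`.
#' Non-decreasing in both `n_required` and the rejection fraction.
#'
#' @param n_required Post-rejection trials required.
#' @param presented_per_session Trials presented (or collected) per session.
#' @param rejection_fraction Fraction of trials rejected, in \[0, 1).
#' @return Integer number of sessions.
#' @export
#' @examples
#' sessions_needed(33, 40, 0.43)    # 2
#' sessions_needed(467, 352.1, 0.593)  # 4
sessions_needed <- function(n_required, presented_per_session,
                            rejection_fraction) {
  if (n_required <= 0 || presented_per_session <= 0) {
    stop("inputs must be positive")
  }
  if (rejection_fraction < 0 || rejection_fraction >= 1) {
    stop("rejection_fraction must lie in [0, 1)")
  }
  as.integer(ceiling(n_required /
                       (presented_per_session * (1 - rejection_fraction))))
}

#' Expected trials surviving rejection
#'
#' @param collected_per_session Trials collected per session.
#' @param rejection_fraction Fraction rejected, in \[0, 1\].
#' @return Expected surviving trial count (fractional).
#' @export
#' @examples
#' expected_surviving_trials(30, 0.43)   # 17.1
expected_surviving_trials <- function(collected_per_session,
                                      rejection_fraction) {
  stopifnot(collected_per_session >= 0,
            rejection_fraction >= 0, rejection_fraction <= 1)
  collected_per_session * (1 - rejection_fraction)
}

#' Published reference constants
#'
#' Summary constants used by the sessions-needed projections, shipped as
#' documented values (the underlying raw datasets are not redistributable):
#'
#' * `wet`: single-session wet-EEG reference values from the ERP CORE
#'   laboratory dataset — SME (uV), mean trials surviving its rejection, and
#'   trials presented/collected per session, for the oddball target and
#'   flanker correct/error ERPs.
#' * `dry_yield`: per-session dry-EEG trial accounting of the two at-home
#'   cohorts — trials collected per session, percent discarded by the staged
#'   rejection, and resulting available trials.
#' * `required_trials`: published post-rejection dry-EEG trial counts needed
#'   to match the wet reference SMEs, per cohort and ERP.
#' * `usability`: published cohort usability summaries (mean/SD SUS composite
#'   score and percent of attempted sessions completed). The underlying
#'   questionnaires and session logs are not available, so these are
#'   constants, not recomputed quantities.
#'
#' @return Named list of data frames.
#' @export
reference_benchmarks <- function() {
  wet <- data.frame(
    erp = c("oddball_target", "flanker_correct", "flanker_error"),
    sme_uv = c(1.83, 0.51, 1.68),
    trials_surviving = c(30.5, 337, 40.1),
    trials_presented = c(40, 352.1, 42),
    stringsAsFactors = FALSE)
  dry_yield <- data.frame(
    cohort = rep(c("younger", "older"), each = 3),
    erp = rep(c("oddball_target", "flanker_correct", "flanker_error"), 2),
    trials_collected = c(30, 117.8, 20.2, 30, 126.2, 6.7),
    pct_discarded = c(43, 59.3, 40, 64.2, 73.9, 61.9),
    trials_available = c(17.1, 47.5, 11.3, 10.7, 32.6, 2.5),
    stringsAsFactors = FALSE)
  required_trials <- data.frame(
    cohort = rep(c("younger", "older"), each = 3),
    erp = rep(c("oddball_target", "flanker_correct", "flanker_error"), 2),
    n_required = c(33, 467, 56, 31, 667, 71),
    stringsAsFactors = FALSE)
  usability <- data.frame(
    cohort = c("younger", "older"),
    sus_mean = c(88.33, 84.53),
    sus_sd = c(10.18, 10.15),
    pct_sessions_complete = c(96, 93),
    stringsAsFactors = FALSE)
  list(wet = wet, dry_yield = dry_yield, required_trials = required_trials,
       usability = usability)
}
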