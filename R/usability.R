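#' Adherence summary from a session manifest
#'
#' Per participant: sessions attempted, percent of attempted sessions with
#' complete data, and cohort-level mean/SD/range of both; plus weekly
#' attempted-session counts, with week boundaries rolling from each
#' participant's own first session date (7-day windows). Participants may
#' attempt more sessions than requested; that surplus is reported, not
#' clipped.
#'
#' @param manifest Data frame with `participant`, `session`, `date`,
#'   `attempted`, `complete` (one row per participant-session-task; a
#'   session-day counts once).
#' @param requested Number of sessions requested per participant (> 0).
#' @return List with `per_participant`, `cohort` (summary stats) and
#'   `weekly` (participant, week, attempted count).
#' @export
adherence_summary <- function(manifest, requested) {
  if (nrow(manifest) == 0) stop("empty manifest")
  if (requested <= 0) stop("requested must be positive")
  days <- unique(manifest[, c("participant", "session", "date", "attempted",
                              "complete")])
  per <- do.call(rbind, lapply(split(days, days$participant), function(d) {
    att <- sum(d$attempted)
    data.frame(participant = d$participant[1], requested = requested,
               attempted = att,
               pct_complete = if (att > 0) 100 * sum(d$complete) / att
                              else NA_real_)
  }))
  rownames(per) <- NULL
  weekly <- do.call(rbind, lapply(split(days, days$participant), function(d) {
    wk <- as.integer(floor(as.numeric(d$date - min(d$date)) / 7)) + 1L
    agg <- stats::aggregate(list(attempted = d$attempted), list(week = wk),
                            sum)
    agg$participant <- d$participant[1]
    agg
  }))
  rownames(weekly) <- NULL
  cohort <- data.frame(
    mean_attempted = mean(per$attempted), sd_attempted = stats::sd(per$attempted),
    min_attempted = min(per$attempted), max_attempted = max(per$attempted),
    mean_pct_complete = mean(per$pct_complete, na.rm = TRUE),
    sd_pct_complete = stats::sd(per$pct_complete, na.rm = TRUE),
    min_pct_complete = min(per$pct_complete, na.rm = TRUE),
    max_pct_complete = max(per$pct_complete, na.rm = TRUE))
  list(per_participant = per, cohort = cohort, weekly = weekly)
}

#' Per-channel session survival
#'
#' Percentage of complete sessions that retain at least one analyzable epoch
#' at each channel after the full rejection procedure, per task and
#' condition.
#'
#' @param reports Data frame binding the `report` components from
#'   [run_rejection_pipeline()] across sessions, with a `task` column.
#' @return Data frame `task`, `condition`, `channel`, `n_sessions`,
#'   `pct_surviving`.
#' @export
channel_survival <- function(reports) {
  if (nrow(reports) == 0) stop("no rejection reports")
  agg <- stats::aggregate(
    list(pct_surviving = reports$survived),
    reports[, c("task", "condition", "channel")],
    function(v) 100 * mean(v))
  n <- stats::aggregate(list(n_sessions = reports$survived),
                        reports[, c("task", "condition", "channel")], length)
  merge(agg, n, sort = TRUE)
}

#' System Usability Scale score
#'
#' Brooke's standard scoring of the 10-item SUS questionnaire: odd items
#' contribute (value - 1), even items (5 - value), the sum scaled by 2.5 to
#' a 0-100 range (granularity 2.5).
#'
#' @param response Integer vector of 10 item scores, each in 1-5 (item order
#'   1-10).
#' @return Score in \[0, 100\].
#' @export
#' @examples
#' sus_score(rep(3, 10))             # 50
#' sus_score(rep(c(5, 1), 5))        # 100
sus_score <- function(response) {
  if (length(response) != 10) stop("SUS needs exactly 10 item scores")
  if (any(response != round(response)) || any(response < 1 | response > 5)) {
    stop("SUS item scores must be integers in 1-5")
  }
  odd <- response[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - response[c(2, 4, 6, 8, 10)]
  2.5 * sum(odd, even)
}

#' One-sided Mann-Whitney U comparison
#'
#' Rank-based comparison of two score groups (e.g. SUS scores of two
#' cohorts). For combined sample sizes up to `exact_max` the p-value is
#' computed by exact permutation enumeration over the observed pooled values
#' (so ties are handled exactly); above that, a normal approximation with
#' tie-corrected variance and continuity correction is used — the regime the
#' study's group sizes fall in.
#'
#' @param group_a,group_b Numeric score vectors (non-empty).
#' @param alternative `"less"` (a tends smaller than b) or `"greater"`.
#' @param exact_max Combined-size threshold for the exact path (default 20).
#' @return List with `U` (the U statistic of `group_a`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' compare_sus(c(1, 2, 3), c(4, 5, 6), "less")  # U = 0, p = 0.05
compare_sus <- function(group_a, group_b,
                        alternative = c("less", "greater"), exact_max = 20) {
  alternative <- match.arg(alternative)
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  if (alternative == "greater") {
    res <- compare_sus(group_b, group_a, "less", exact_max)
    return(list(U = na * nb - res$U, p_value = res$p_value,
                method = res$method))
  }
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (stats::sd(pooled) == 0) {
    return(list(U = U, p_value = 0.5, method = "degenerate"))
  }
  if (na + nb <= exact_max) {
    combs <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(u_all <= U)
    list(U = U, p_value = p, method = "exact")
  } else {
    n <- na + nb
    ties <- table(rk)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu + 0.5) / sqrt(sig2)
    list(U = U, p_value = stats::pnorm(z), method = "normal")
  }
}

#' Simulate SUS questionnaire responses
#'
#' Draws plausible 10-item SUS responses whose composite scores concentrate
#' around a target mean: item-level responses are drawn around a latent
#' per-respondent satisfaction level and clipped to the 1-5 scale. Used by
#' the usability analysis scripts; real questionnaire data are read from CSV
#' instead.
#'
#' @param n Number of respondents.
#' @param target_mean Target mean composite score (0-100).
#' @param sd_between Between-respondent SD of the latent satisfaction.
#' @return Matrix `n x 10` of item scores.
#' @export
simulate_sus_responses <- function(n, target_mean = 85, sd_between = 10) {
  latent <- stats::rnorm(n, target_mean / 25, sd_between / 25)
  out <- matrix(0L, n, 10)
  for (i in seq_len(n)) {
    item <- latent[i] + stats::rnorm(10, 0, 0.5)
    item <- pmin(4, pmax(0, round(item)))
    odd <- item[c(1, 3, 5, 7, 9)] + 1
    even <- 5 - item[c(2, 4, 6, 8, 10)]
    out[i, c(1, 3, 5, 7, 9)] <- as.integer(odd)
    out[i, c(2, 4, 6, 8, 10)] <- as.integer(even)
  }
  out
}
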