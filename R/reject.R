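#' Rejection thresholds
#'
#' Default thresholds of the staged per-channel epoch rejection: absolute
#' amplitude 100 uV (strict inequality), minimum correlation to the session
#' average 0.25, first z-score gate 15, Hurst floor 0.65, spectral-peak floor
#' 0.1, final z-score gate 4.
#'
#' @param amplitude_uv,min_correlation,z_gross,hurst_min,spectral_peak_min,z_final
#'   Stage thresholds.
#' @param loo_correlation Use leave-one-out session averages in the
#'   correlation stage (default `FALSE`: the epoch under test is included in
#'   the session average, matching the plain reading of the procedure).
#' @return Named list of thresholds.
#' @export
rejection_thresholds <- function(amplitude_uv = 100, min_correlation = 0.25,
                                 z_gross = 15, hurst_min = 0.65,
                                 spectral_peak_min = 0.1, z_final = 4,
                                 loo_correlation = FALSE) {
  if (amplitude_uv <= 0) stop("amplitude threshold must be positive")
  if (min_correlation < -1 || min_correlation > 1) {
    stop("correlation threshold must lie in [-1, 1]")
  }
  list(amplitude_uv = amplitude_uv, min_correlation = min_correlation,
       z_gross = z_gross, hurst_min = hurst_min,
       spectral_peak_min = spectral_peak_min, z_final = z_final,
       loo_correlation = loo_correlation)
}

#' Reject epochs by absolute amplitude
#'
#' Marks (epoch, channel) entries whose maximum absolute voltage exceeds the
#' threshold (strictly) as rejected. Epochs must be baseline-adjusted first.
#'
#' @param epochs A baseline-adjusted `EpochSet`.
#' @param threshold_uv Amplitude threshold in uV (default 100).
#' @return The `EpochSet` with an updated retention mask.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 100) {
  if (threshold_uv <= 0) stop("amplitude threshold must be positive")
  peak <- apply(abs(epochs$data), c(1, 2), max)
  epochs$retained <- epochs$retained & (peak <= threshold_uv)
  epochs
}

#' Reject epochs weakly correlated with the session average
#'
#' For each retained (epoch, channel) entry, the epoch's time series is
#' Pearson-correlated with the mean of the retained epochs of the same
#' condition and channel (the "session average", including the epoch under
#' test unless `loo = TRUE`); entries with r below the threshold are
#' rejected. Zero-variance epochs count as r = 0 and are rejected. Groups
#' with fewer than two retained epochs are skipped with a warning.
#'
#' @param epochs A baseline-adjusted `EpochSet` (amplitude stage applied).
#' @param min_r Correlation threshold (default 0.25).
#' @param loo Leave the epoch under test out of the session average.
#' @return The `EpochSet` with an updated retention mask.
#' @export
reject_low_correlation <- function(epochs, min_r = 0.25, loo = FALSE) {
  nch <- dim(epochs$data)[2]
  for (cond in unique(epochs$condition)) {
    in_cond <- epochs$condition == cond
    for (ch in seq_len(nch)) {
      rows <- which(in_cond & epochs$retained[, ch])
      if (length(rows) < 2) {
        if (length(rows) > 0) {
          warning(sprintf(
            "correlation stage skipped for %s/%s: < 2 retained epochs",
            epochs$channels[ch], cond))
        }
        next
      }
      mat <- epochs$data[rows, ch, , drop = FALSE]
      dim(mat) <- c(length(rows), dim(epochs$data)[3])
      avg <- colMeans(mat)
      for (i in seq_along(rows)) {
        ref <- if (loo) (avg * length(rows) - mat[i, ]) / (length(rows) - 1)
               else avg
        r <- if (stats::sd(mat[i, ]) == 0 || stats::sd(ref) == 0) 0
             else stats::cor(mat[i, ], ref)
        if (r < min_r) epochs$retained[rows[i], ch] <- FALSE
      }
    }
  }
  epochs
}

#' Staged z-score rejection
#'
#' Applies the three metric-based stages in order: (1) any |z| > `z_gross`
#' (default 15) in any of the seven z-scored metrics; (2) absolute
#' thresholds, Hurst exponent < `hurst_min` (0.65) or spectral peak <
#' `spectral_peak_min` (0.1); (3) z-scores recomputed over the epochs
#' remaining after stages 1-2, any |z| > `z_final` (4). z thresholds are
#' applied two-sided: gradient- and power-type artifacts can be extreme in
#' either direction. The retention mask shrinks monotonically; removing every
#' epoch is allowed (the session is then simply not survived at that
#' channel).
#'
#' @param metrics Metric table from [compute_epoch_metrics()], computed on
#'   the currently retained epochs.
#' @param epochs The matching `EpochSet`.
#' @param thresholds A [rejection_thresholds()] list.
#' @return List with the updated `EpochSet` and per-stage removal tallies
#'   (`removed`: data frame epoch/channel/stage).
#' @export
zscore_staged_reject <- function(metrics, epochs,
                                 thresholds = rejection_thresholds()) {
  zcols <- grep("^z_", names(metrics), value = TRUE)
  chidx <- match(metrics$channel, epochs$channels)
  removed <- list()
  mark <- function(rows, stage) {
    for (r in rows) {
      epochs$retained[metrics$epoch[r], chidx[r]] <<- FALSE
    }
    if (length(rows)) {
      removed[[stage]] <<- data.frame(epoch = metrics$epoch[rows],
                                      channel = metrics$channel[rows],
                                      stage = stage)
    }
  }
  zmax <- do.call(pmax, c(lapply(metrics[zcols], abs), list(na.rm = TRUE)))
  mark(which(zmax > thresholds$z_gross), "z_gross")
  alive <- rep(TRUE, nrow(metrics))
  alive[which(zmax > thresholds$z_gross)] <- FALSE

  bad_abs <- alive & ((!is.na(metrics$hurst) &
                         metrics$hurst < thresholds$hurst_min) |
                        metrics$spectral_peak < thresholds$spectral_peak_min)
  mark(which(bad_abs), "hurst_spectral")
  alive <- alive & !bad_abs

  m2 <- add_zscores(metrics[alive, setdiff(names(metrics), zcols)])
  z2 <- grep("^z_", names(m2), value = TRUE)
  zmax2 <- do.call(pmax, c(lapply(m2[z2], abs), list(na.rm = TRUE)))
  rows2 <- which(alive)[zmax2 > thresholds$z_final]
  mark(rows2, "z_final")

  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(epoch = integer(), channel = character(), stage = character())
  rownames(removed) <- NULL
  list(epochs = epochs, removed = removed)
}

#' Run the full staged rejection pipeline
#'
#' Applies the stages in the study's order — absolute amplitude, correlation
#' to the session average, gross z-score gate, absolute Hurst/spectral-peak
#' thresholds, final recomputed z-score gate — and tallies removals per
#' (channel, condition) and stage in a rejection report. Deterministic:
#' identical input gives an identical report.
#'
#' @param epochs A baseline-adjusted `EpochSet`.
#' @param thresholds A [rejection_thresholds()] list.
#' @param analysis_conditions Conditions counting towards session survival
#'   (default: every condition present).
#' @return List with `epochs` (final retention mask) and `report`, a data
#'   frame with one row per (channel, condition): epochs in, removals at each
#'   stage, epochs out, and a `survived` flag (>= 1 retained epoch of the
#'   condition).
#' @export
run_rejection_pipeline <- function(epochs,
                                   thresholds = rejection_thresholds(),
                                   analysis_conditions = NULL) {
  count_mask <- function(ep) {
    out <- expand.grid(channel = ep$channels,
                       condition = unique(ep$condition),
                       stringsAsFactors = FALSE)
    out$n <- mapply(function(ch, cond) {
      sum(ep$retained[ep$condition == cond, match(ch, ep$channels)])
    }, out$channel, out$condition)
    out
  }
  n_in <- count_mask(epochs)
  e1 <- reject_amplitude(epochs, thresholds$amplitude_uv)
  n1 <- count_mask(e1)
  e2 <- withCallingHandlers(
    reject_low_correlation(e1, thresholds$min_correlation,
                           thresholds$loo_correlation),
    warning = function(w) invokeRestart("muffleWarning"))
  n2 <- count_mask(e2)
  metrics <- compute_epoch_metrics(e2)
  zs <- zscore_staged_reject(metrics, e2, thresholds)
  e3 <- zs$epochs
  n_out <- count_mask(e3)

  stage_n <- function(stage) {
    sub <- zs$removed[zs$removed$stage == stage, , drop = FALSE]
    vapply(seq_len(nrow(n_in)), function(i) {
      sum(sub$channel == n_in$channel[i] &
            e3$condition[sub$epoch] == n_in$condition[i])
    }, 0L)
  }
  report <- data.frame(
    participant = epochs$participant, session = epochs$session,
    channel = n_in$channel, condition = n_in$condition,
    n_in = n_in$n,
    rej_amplitude = n_in$n - n1$n,
    rej_correlation = n1$n - n2$n,
    rej_z_gross = stage_n("z_gross"),
    rej_hurst_spectral = stage_n("hurst_spectral"),
    rej_z_final = stage_n("z_final"),
    n_out = n_out$n, stringsAsFactors = FALSE)
  report$survived <- report$n_out >= 1
  if (!is.null(analysis_conditions)) {
    report$analysis <- report$condition %in% analysis_conditions
  }
  list(epochs = e3, report = report)
}
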