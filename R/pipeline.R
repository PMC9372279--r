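#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the study's values
#' as defaults: the 0.25-40 Hz filter band, the \[-500, 1000) ms epoch
#' window, task-specific baselines and score windows, and the rejection
#' thresholds (100 uV, r 0.25, z 15, Hurst 0.65, spectral peak 0.1, z 4).
#' Round-trips losslessly through JSON.
#'
#' @param input_dir Directory of recordings (`write_recording()` layout plus
#'   `manifest.json`).
#' @param output_dir Directory for result tables.
#' @param task `"oddball"` or `"flanker"`.
#' @param cohort `"younger"` or `"older"`.
#' @param filter_band Band edges in Hz.
#' @param thresholds A [rejection_thresholds()] list.
#' @param seed Seed recorded in the run log.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = "results",
                            task = c("oddball", "flanker"),
                            cohort = c("younger", "older"),
                            filter_band = c(0.25, 40),
                            thresholds = rejection_thresholds(),
                            seed = 1L) {
  task <- match.arg(task)
  cohort <- match.arg(cohort)
  if (filter_band[1] <= 0 || filter_band[2] <= filter_band[1]) {
    stop("invalid filter band")
  }
  do.call(rejection_thresholds, thresholds[setdiff(names(thresholds),
                                                   "loo_correlation")])
  structure(list(input_dir = input_dir, output_dir = output_dir, task = task,
                 cohort = cohort, filter_band = filter_band,
                 epoch_window_ms = c(-500, 1000),
                 baseline_ms = default_baseline(task),
                 score = score_window(task, cohort),
                 thresholds = thresholds, seed = seed),
            class = "PipelineConfig")
}

#' Process one session end to end
#'
#' Filter, epoch, baseline-adjust and reject a single continuous recording,
#' returning the cleaned epochs, the rejection report and the per-trial
#' window-mean scores for each analysis condition.
#'
#' @param recording A `ContinuousRecording`.
#' @param config A [pipeline_config()].
#' @return List with `epochs`, `report`, `scores` (named by condition).
#' @export
process_session <- function(recording, config) {
  filt <- bandpass_filter(recording, config$filter_band[1],
                          config$filter_band[2])
  locking <- if (config$task == "oddball") "stimulus" else "response"
  ep <- extract_epochs(filt, locking = locking,
                       window_ms = config$epoch_window_ms)
  ep <- baseline_adjust(ep, config$baseline_ms)
  rej <- run_rejection_pipeline(ep, config$thresholds,
                                analysis_conditions = config$score$conditions)
  scores <- lapply(config$score$conditions, function(cond) {
    window_scores(rej$epochs, config$score, cond)
  })
  list(epochs = rej$epochs, report = rej$report,
       scores = stats::setNames(scores, config$score$conditions))
}

#' Run the full analysis pipeline over a recorded cohort
#'
#' Executes preprocess, rejection, SME aggregation and reporting over every
#' complete session of the configured task in `input_dir`: reads the
#' manifest and each EDF + event table, processes sessions with
#' [process_session()], aggregates per-participant scores in recording
#' order, and derives the group SME curve, the trials needed to match the
#' wet-EEG reference SME, the measured rejection fraction, the
#' sessions-needed projection, per-channel session survival and the
#' adherence summary. All tables are written under `output_dir` as CSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @return The analysis bundle, invisibly: list with `reports`, `curves`,
#'   `summary`, `survival`, `adherence`, `erp` (grand-median ERP).
#' @export
run_pipeline <- function(config) {
  manifest <- read_manifest(file.path(config$input_dir, "manifest.json"))
  rows <- manifest[manifest$task == config$task & manifest$complete, ]
  if (nrow(rows) == 0) stop("no complete ", config$task, " sessions found")
  reports <- list()
  scores <- list()
  erps <- list()
  for (i in seq_len(nrow(rows))) {
    base <- file.path(config$input_dir,
                      sprintf("p%02d_s%02d_%s", rows$participant[i],
                              rows$session[i], config$task))
    rec <- read_recording(base)
    rec$participant <- rows$participant[i]
    rec$session <- rows$session[i]
    ps <- process_session(rec, config)
    ps$report$task <- config$task
    reports[[i]] <- ps$report
    for (cond in names(ps$scores)) {
      key <- sprintf("p%02d", rows$participant[i])
      scores[[cond]][[key]] <- rbind(scores[[cond]][[key]],
                                     ps$scores[[cond]])
    }
    erps[[i]] <- median_erp(ps$epochs, config$score$conditions[1])[[1]]
  }
  reports <- do.call(rbind, reports)
  bench <- reference_benchmarks()$wet
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  curves <- list()
  summary <- list(task = config$task, cohort = config$cohort,
                  seed = config$seed, n_sessions = nrow(rows))
  for (cond in config$score$conditions) {
    sc <- scores[[cond]]
    sc <- sc[vapply(sc, nrow, 0L) > 0]
    ref <- bench$sme_uv[match(paste0(config$task, "_", cond), bench$erp)]
    if (length(sc) >= 2) {
      curve <- group_sme_curve(sc)
      curves[[cond]] <- curve
      utils::write.csv(curve, file.path(config$output_dir,
                                        paste0("sme_curve_", cond, ".csv")),
                       row.names = FALSE)
      n_req <- if (is.na(ref)) NA_integer_ else trials_to_reference(curve, ref)
    } else {
      n_req <- NA_integer_
    }
    ana <- reports[reports$condition == cond, ]
    rej_frac <- 1 - sum(ana$n_out[ana$channel == config$score$channel]) /
      sum(ana$n_in[ana$channel == config$score$channel])
    presented <- mean(ana$n_in[ana$channel == config$score$channel])
    summary[[cond]] <- list(
      reference_sme_uv = ref, n_required = n_req,
      rejection_fraction = rej_frac,
      trials_per_session = presented,
      sessions_needed = if (is.na(n_req) || rej_frac >= 1) NA_integer_ else
        sessions_needed(n_req, presented, rej_frac))
  }
  grand <- Reduce(`+`, erps) / length(erps)
  surv <- channel_survival(reports)
  adh <- adherence_summary(manifest[manifest$task == config$task, ],
                           requested = max(manifest$session))
  utils::write.csv(reports, file.path(config$output_dir,
                                      "rejection_report.csv"),
                   row.names = FALSE)
  utils::write.csv(surv, file.path(config$output_dir,
                                   "channel_survival.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(reports = reports, curves = curves, summary = summary,
                 survival = surv, adherence = adh, erp = grand))
}
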