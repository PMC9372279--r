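#!/usr/bin/env Rscript
# Stage 3: staged per-channel epoch rejection.
#
# Stages in order: absolute amplitude > 100 uV; correlation to the session
# average < 0.25; any metric |z| > 15; Hurst < 0.65 or spectral peak < 0.1;
# recomputed |z| > 4. Writes the updated epoch containers, a per-session x
# channel x condition rejection report, and per-channel session survival.

suppressMessages(library(dryerp))

in_root <- "results/epochs"
for (cohort in c("younger", "older")) {
  files <- list.files(file.path(in_root, cohort), pattern = "\\.json$")
  reports <- list()
  for (f in files) {
    base <- file.path(in_root, cohort, sub("\\.json$", "", f))
    task <- sub(".*_(oddball|flanker)$", "\\1", base)
    ep <- read_epochs(base)
    ana <- score_window(task, cohort)$conditions
    rej <- run_rejection_pipeline(ep, analysis_conditions = ana)
    write_epochs(rej$epochs, base)          # persist updated retention mask
    rej$report$task <- task
    reports[[f]] <- rej$report
  }
  reports <- do.call(rbind, reports)
  rownames(reports) <- NULL
  utils::write.csv(reports,
                   file.path(in_root, cohort, "rejection_report.csv"),
                   row.names = FALSE)
  surv <- channel_survival(reports[reports$analysis, ])
  utils::write.csv(surv, file.path(in_root, cohort, "channel_survival.csv"),
                   row.names = FALSE)
  for (task in c("oddball", "flanker")) {
    sub <- reports[reports$task == task & reports$analysis, ]
    cat(sprintf("%s %s: %.1f%% of analysis epochs discarded, %.0f%% of\n",
                cohort, task, 100 * (1 - sum(sub$n_out) / sum(sub$n_in)),
                100 * mean(sub$survived)))
    cat("  session-channel entries survived with >= 1 epoch\n")
  }
}
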