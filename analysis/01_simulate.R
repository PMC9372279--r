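#!/usr/bin/env Rscript
# Stage 1: generate the synthetic at-home study data.
#
# Two cohorts (younger / older) at desk scale: 5 participants x 4 sessions
# per task, written as EDF + event CSV per session plus a JSON manifest.
# Cohort structure, ERP morphology, noise and artifact regime come from the
# package defaults (see make_cohort_config and the methods vignette); only
# the cohort size is reduced here to keep the workflow fast.

suppressMessages(library(dryerp))

out_root <- "results/data"
for (cohort in c("younger", "older")) {
  cfg <- make_cohort_config(cohort, list(n_participants = 5L,
                                         n_sessions = 4L, seed = 2024L))
  dir <- file.path(out_root, cohort)
  sim <- simulate_cohort(cfg, out_dir = dir)
  n_rec <- length(sim$recordings)
  n_days <- nrow(unique(sim$manifest[, c("participant", "session")]))
  complete <- mean(unique(sim$manifest[, c("participant", "session",
                                           "complete")])$complete)
  cat(sprintf(
    "%s cohort: %d session-days, %.0f%% complete, %d recordings -> %s\n",
    cohort, n_days, 100 * complete, n_rec, dir))
}
cat("done; continuous data and manifests under", out_root, "\n")
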