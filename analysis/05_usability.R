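#!/usr/bin/env Rscript
# Stage 5: adherence and usability accounting.
#
# Adherence is computed from full-scale cohort manifests (manifest-only
# simulation at the studies' sizes: 30 x 23 younger, 50 x 15 older session
# days per task). SUS questionnaires are simulated around the published
# cohort means (the real questionnaires are not available; the published
# values are constants, see reference_benchmarks()), scored with Brooke's
# formula, and compared with the one-sided Mann-Whitney U test.

suppressMessages(library(dryerp))

out_root <- "results/usability"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
set.seed(2024)
bench <- reference_benchmarks()$usability

rows <- list()
for (cohort in c("younger", "older")) {
  cfg <- make_cohort_config(cohort)
  m <- simulate_cohort(cfg, manifest_only = TRUE)$manifest
  adh <- adherence_summary(m[m$task == "oddball", ],
                           requested = cfg$n_sessions)
  utils::write.csv(adh$per_participant,
                   file.path(out_root, paste0("adherence_", cohort, ".csv")),
                   row.names = FALSE)
  utils::write.csv(adh$weekly,
                   file.path(out_root, paste0("weekly_", cohort, ".csv")),
                   row.names = FALSE)
  rows[[cohort]] <- cbind(cohort = cohort, adh$cohort)
  cat(sprintf(
    "%s: mean %.1f sessions attempted (SD %.1f), %.1f%% complete (SD %.1f)\n",
    cohort, adh$cohort$mean_attempted, adh$cohort$sd_attempted,
    adh$cohort$mean_pct_complete, adh$cohort$sd_pct_complete))
}
utils::write.csv(do.call(rbind, rows),
                 file.path(out_root, "adherence_cohorts.csv"),
                 row.names = FALSE)

# SUS: simulated questionnaires at the published cohort targets,
# study-sized respondent groups (18 younger, 32 older debriefed)
young_resp <- simulate_sus_responses(18, bench$sus_mean[bench$cohort ==
                                                          "younger"])
old_resp <- simulate_sus_responses(32, bench$sus_mean[bench$cohort ==
                                                        "older"])
young <- apply(young_resp, 1, sus_score)
old <- apply(old_resp, 1, sus_score)
mw <- compare_sus(old, young, "less")   # does age lower usability?
sus <- data.frame(cohort = c("younger", "older"),
                  n = c(length(young), length(old)),
                  mean_sus = c(mean(young), mean(old)),
                  sd_sus = c(sd(young), sd(old)))
utils::write.csv(sus, file.path(out_root, "sus_scores.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(U = mw$U, p_value = mw$p_value,
                          method = mw$method,
                          alternative = "older < younger"),
                     file.path(out_root, "sus_comparison.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("SUS: younger %.1f (n=%d), older %.1f (n=%d); U = %g, p = %.3f\n",
            mean(young), length(young), mean(old), length(old),
            mw$U, mw$p_value))
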