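#!/usr/bin/env Rscript
# Stage 4: SME aggregation curves and sessions-needed projections.
#
# Per-trial window-mean scores (Pz 300-400 / 400-500 ms for oddball targets
# by cohort; FCz 0-100 ms for flanker correct and error trials) are pooled
# per participant in recording order across sessions. Group SME curves, the
# trial counts needed to reach the wet-EEG reference SMEs, and the projected
# number of at-home sessions (from each cohort's measured rejection
# fraction) are written under results/sme/. The published-constant
# projections (2/4/3 younger, 3 older oddball) are recomputed alongside.

suppressMessages(library(dryerp))

in_root <- "results/epochs"
out_root <- "results/sme"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
bench <- reference_benchmarks()

summary_rows <- list()
for (cohort in c("younger", "older")) {
  reports <- utils::read.csv(file.path(in_root, cohort,
                                       "rejection_report.csv"))
  for (task in c("oddball", "flanker")) {
    sw <- score_window(task, cohort)
    for (cond in sw$conditions) {
      files <- list.files(file.path(in_root, cohort),
                          pattern = paste0("_", task, "\\.json$"))
      by_part <- list()
      for (f in files) {
        ep <- read_epochs(file.path(in_root, cohort, sub("\\.json$", "", f)))
        sc <- window_scores(ep, sw, cond)
        key <- sprintf("p%02d", ep$participant)
        by_part[[key]] <- rbind(by_part[[key]], sc)
      }
      by_part <- by_part[vapply(by_part, nrow, 0L) > 0]
      erp <- paste0(task, "_", cond)
      erp <- sub("oddball_target", "oddball_target", erp)
      ref <- bench$wet$sme_uv[match(erp, bench$wet$erp)]
      curve <- group_sme_curve(by_part)
      utils::write.csv(curve, file.path(out_root, sprintf(
        "sme_curve_%s_%s_%s.csv", cohort, task, cond)), row.names = FALSE)
      n_req <- if (is.na(ref)) NA_integer_ else trials_to_reference(curve, ref)
      sub <- reports[reports$condition == cond &
                       reports$channel == sw$channel, ]
      rej_frac <- 1 - sum(sub$n_out) / sum(sub$n_in)
      presented <- mean(sub$n_in)
      sessions <- if (is.na(n_req)) NA_integer_ else
        sessions_needed(n_req, presented, rej_frac)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        cohort = cohort, task = task, condition = cond,
        reference_sme_uv = ref, n_required = n_req,
        rejection_fraction = round(rej_frac, 3),
        trials_per_session = presented, sessions_needed = sessions)
      cat(sprintf(
        "%s %s/%s: SME reaches %s uV at n = %s; %.1f%% rejected -> %s sessions\n",
        cohort, task, cond, format(ref), format(n_req), 100 * rej_frac,
        format(sessions)))
    }
  }
}
summary <- do.call(rbind, summary_rows)
utils::write.csv(summary, file.path(out_root, "sme_summary.csv"),
                 row.names = FALSE)

# published-constant projections (these are the headline numbers; the older
# flanker rows are not derivable from the ceiling formula and are omitted)
pub <- data.frame(
  cohort = c("younger", "younger", "younger", "older"),
  erp = c("oddball_target", "flanker_correct", "flanker_error",
          "oddball_target"))
pub$sessions <- mapply(function(cohort, erp) {
  sessions_needed(
    bench$required_trials$n_required[bench$required_trials$cohort == cohort &
                                       bench$required_trials$erp == erp],
    bench$wet$trials_presented[bench$wet$erp == erp],
    bench$dry_yield$pct_discarded[bench$dry_yield$cohort == cohort &
                                    bench$dry_yield$erp == erp] / 100)
}, pub$cohort, pub$erp)
utils::write.csv(pub, file.path(out_root, "published_projections.csv"),
                 row.names = FALSE)
cat("\npublished-constant projections:\n")
print(pub, row.names = FALSE)
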