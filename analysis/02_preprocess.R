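#!/usr/bin/env Rscript
# Stage 2: preprocess every complete recording.
#
# Band-pass 0.25-40 Hz (4th-order Butterworth, zero-phase), epoch extraction
# over [-500, 1000) ms (stimulus-locked oddball, response-locked flanker),
# and per-channel baseline adjustment ([-100, 0) ms for oddball,
# [-500, -400) ms for flanker). Epochs are persisted as float64 + JSON
# containers under results/epochs/.

suppressMessages(library(dryerp))

in_root <- "results/data"
out_root <- "results/epochs"
for (cohort in c("younger", "older")) {
  manifest <- read_manifest(file.path(in_root, cohort, "manifest.json"))
  done <- 0
  for (i in which(manifest$complete)) {
    key <- sprintf("p%02d_s%02d_%s", manifest$participant[i],
                   manifest$session[i], manifest$task[i])
    rec <- read_recording(file.path(in_root, cohort, key))
    rec$participant <- manifest$participant[i]
    rec$session <- manifest$session[i]
    task <- manifest$task[i]
    filt <- bandpass_filter(rec)
    locking <- if (task == "oddball") "stimulus" else "response"
    ep <- extract_epochs(filt, locking = locking)
    ep <- baseline_adjust(ep, default_baseline(task))
    dir.create(file.path(out_root, cohort), recursive = TRUE,
               showWarnings = FALSE)
    write_epochs(ep, file.path(out_root, cohort, key))
    done <- done + 1
  }
  cat(sprintf("%s cohort: %d sessions preprocessed -> %s/%s\n",
              cohort, done, out_root, cohort))
}
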