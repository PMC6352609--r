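#!/usr/bin/env Rscript
# Band-pass (8-30 Hz, 5th-order Butterworth, zero-phase) every simulated
# session and cut the classification epochs: one 3.5-s kinesthetic epoch per
# green cue (starting 0.5 s after it) and one 3.5-s rest epoch per red cue
# (starting 2.5 s after it).

library(kmibci)

in_dir <- "results/cohort"
out <- "results/epochs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

subjects <- read_subjects(file.path(in_dir, "subjects.csv"))$subject_id
for (id in subjects) {
  ses <- read_session(file.path(in_dir, paste0(id, ".edf")),
                      file.path(in_dir, paste0(id, "_events.tsv")))
  ep <- extract_epochs(bandpass(ses))
  saveRDS(ep, file.path(out, paste0(id, "_epochs.rds")))
  cat(sprintf("%s: %d epochs of %d channels x %d samples (%s)\n",
              id, dim(ep$data)[1], dim(ep$data)[2], dim(ep$data)[3],
              paste(names(table(ep$labels)), table(ep$labels),
                    sep = "=", collapse = ", ")))
}
cat("Epoch sets written to", out, "\n")
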