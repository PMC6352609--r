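#!/usr/bin/env Rscript
# Evaluate the four motor-imagery-vs-rest classifiers (CSP+LDA, MDRM,
# gfMDRM, TS+LR) per subject under stratified 4-fold cross-validation and
# tabulate per-fold and per-subject accuracy.

library(kmibci)
cfg_file <- yaml::read_yaml(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "config.yaml"))

in_dir <- "results/epochs"
dir.create("results", showWarnings = FALSE)

files <- sort(list.files(in_dir, "_epochs\\.rds$", full.names = TRUE))
rows <- list()
for (f in files) {
  id <- sub("_epochs\\.rds$", "", basename(f))
  ep <- readRDS(f)
  for (m in cfg_file$methods) {
    cv <- suppressWarnings(
      crossval_accuracy(ep, m, k = cfg_file$k_folds, seed = 42))
    rows[[length(rows) + 1]] <- cbind(subject_id = id, method = m, cv$folds)
    cat(sprintf("%s %-8s mean %.3f (min %.3f, max %.3f)\n",
                id, m, cv$mean, cv$min, cv$max))
  }
}
acc <- do.call(rbind, rows)
utils::write.csv(acc, "results/accuracy_folds.csv", row.names = FALSE)

summ <- aggregate(accuracy ~ subject_id + method, acc, mean)
names(summ)[3] <- "mean_accuracy"
summ$min_accuracy <- aggregate(accuracy ~ subject_id + method, acc, min)$accuracy
summ$max_accuracy <- aggregate(accuracy ~ subject_id + method, acc, max)$accuracy
utils::write.csv(summ, "results/accuracy_summary.csv", row.names = FALSE)
jsonlite::write_json(
  lapply(split(summ, summ$method), function(d)
    list(mean = mean(d$mean_accuracy), min = min(d$mean_accuracy),
         max = max(d$mean_accuracy))),
  "results/accuracy_summary.json", auto_unbox = TRUE, digits = NA)

cat("\nCohort mean accuracy by method:\n")
print(aggregate(mean_accuracy ~ method, summ, mean))

jsonlite::write_json(
  list(stage = "classify", cv_seed = 42, methods = cfg_file$methods,
       files = as.list(tools::md5sum(c("results/accuracy_folds.csv",
                                       "results/accuracy_summary.csv")))),
  "results/manifest_classify.json", auto_unbox = TRUE, digits = NA)
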