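#!/usr/bin/env Rscript
# Questionnaire scoring, subject grouping and the inferential battery:
# accuracy-score and accuracy-factor correlations (Pearson + Spearman, with
# Benjamini-Hochberg FDR control at q = 0.20), imagery-quality (K/V) and
# performance/manual-activity group comparisons (Welch's t, Mann-Whitney U,
# Glass's Delta).

library(kmibci)

records <- read_subjects("results/cohort/subjects.csv")
summ <- utils::read.csv("results/accuracy_summary.csv")

# per-method accuracy vectors aligned with the subject table
acc_by_method <- lapply(split(summ, summ$method), function(d)
  d$mean_accuracy[match(records$subject_id, d$subject_id)])

## 1. correlation tables (scores + personal factors)
vars <- c("kmi_score", "vmi_score", "kmi_hand_score", "vmi_hand_score",
          "age", "education_years", "freq_manual", "freq_sport", "freq_music")
tab <- run_correlation_table(records, acc_by_method, variables = vars)
utils::write.csv(tab, "results/correlations.csv", row.names = FALSE)
cat("Correlation table (best classifier, Pearson):\n")
best <- names(which.max(vapply(acc_by_method, mean, 0)))
print(subset(tab, method == best & type == "pearson"),
      row.names = FALSE, digits = 3)

## 2. group assignments
scores <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
  as.data.frame(score_miq(records[i, ]))))
acc_best <- acc_by_method[[best]]
groups <- data.frame(
  subject_id = records$subject_id,
  kmi_score = scores$kmi_score, vmi_score = scores$vmi_score,
  accuracy = acc_best,
  kv_group = mapply(categorize_kv, scores$kmi_score, scores$vmi_score),
  perf_group = split_perf(acc_best),
  manual_group = split_manual(records$freq_manual))
utils::write.csv(groups, "results/groups.csv", row.names = FALSE)
cat(sprintf("\nGroups (classifier: %s): %s\n", best,
            paste(names(table(groups$manual_group)),
                  table(groups$manual_group), sep = "=", collapse = ", ")))

## 3. two-group comparisons on accuracy
compare <- function(a, b, label) {
  if (length(a) < 2 || length(b) < 2) {
    cat(sprintf("%s: group too small (n=%d vs %d), skipped\n",
                label, length(a), length(b)))
    return(NULL)
  }
  w <- welch_t(a, b); u <- mann_whitney_u(a, b); g <- glass_delta(a, b)
  cat(sprintf("%s: Welch p=%.3f, U p=%.3f, Glass Delta=%.2f\n",
              label, w$p_value, u$p_value, g$estimate))
  data.frame(comparison = label, welch_t = w$estimate, welch_p = w$p_value,
             u = u$estimate, u_p = u$p_value, glass_delta = g$estimate,
             n1 = length(a), n2 = length(b))
}
out <- list(
  compare(acc_best[groups$perf_group == "Perf+"],
          acc_best[groups$perf_group == "Perf-"], "Perf+ vs Perf-"),
  compare(acc_best[groups$manual_group == "Manual+"],
          acc_best[groups$manual_group == "Manual-"], "Manual+ vs Manual-"))
# all pairs of K/V categories present with n >= 2
kvs <- names(which(table(groups$kv_group) >= 2))
if (length(kvs) >= 2) {
  for (i in seq_along(kvs)[-length(kvs)]) for (j in (i + 1):length(kvs))
    out[[length(out) + 1]] <- compare(acc_best[groups$kv_group == kvs[i]],
                                      acc_best[groups$kv_group == kvs[j]],
                                      paste(kvs[i], "vs", kvs[j]))
}
out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
if (!is.null(out)) utils::write.csv(out, "results/group_tests.csv", row.names = FALSE)

# normality checks backing the use of Pearson correlation
cat(sprintf("\nShapiro-Wilk p: accuracy %.3f, KMI score %.3f, VMI score %.3f\n",
            shapiro_wilk(acc_best)$p_value,
            shapiro_wilk(scores$kmi_score)$p_value,
            shapiro_wilk(scores$vmi_score)$p_value))
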