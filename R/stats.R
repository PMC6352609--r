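#' Score the MIQ-RS questionnaire
#'
#' The kinesthetic (resp. visual) score is the mean of the seven kinesthetic
#' (resp. visual) item ratings, linearly rescaled from the 1-7 answer range
#' to 0-100: `score = (mean(items) - 1) / 6 * 100`. Subset scores (e.g. the
#' hand- or arm-related items) use the same rescaling over declared item
#' index lists; which items are hand- or arm-related is a configuration
#' choice, not an authoritative mapping.
#'
#' @param record One subject row (data.frame or list) with fields K1..K7 and
#'   V1..V7, each an integer in 1..7.
#' @param subsets Named list of item-index vectors (indices 1..7 within each
#'   scale); defaults: `hand = c(2, 4, 6)`, `arm = c(1, 2, 4, 6, 7)`.
#' @return List with `kmi_score`, `vmi_score`, and
#'   `kmi_<subset>_score` / `vmi_<subset>_score` per subset, all in [0, 100].
#' @export
score_miq <- function(record, subsets = list(hand = c(2, 4, 6),
                                             arm = c(1, 2, 4, 6, 7))) {
  kin <- as.numeric(unlist(record[paste0("K", 1:7)]))
  vis <- as.numeric(unlist(record[paste0("V", 1:7)]))
  if (anyNA(kin) || anyNA(vis)) stop("missing MIQ-RS answer(s)")
  if (any(c(kin, vis) < 1 | c(kin, vis) > 7)) stop("MIQ-RS answers must lie in 1..7")
  rescale <- function(x) (mean(x) - 1) / 6 * 100
  out <- list(kmi_score = rescale(kin), vmi_score = rescale(vis))
  for (nm in names(subsets)) {
    out[[paste0("kmi_", nm, "_score")]] <- rescale(kin[subsets[[nm]]])
    out[[paste0("vmi_", nm, "_score")]] <- rescale(vis[subsets[[nm]]])
  }
  out
}

#' Imagery-quality group labels
#'
#' A KMI (or VMI) score counts as positive when it is greater than or equal
#' to 70, yielding the four groups K+V+, K+V-, K-V+, K-V-.
#'
#' @param kmi_score,vmi_score Scores in [0, 100].
#' @return One of "K+V+", "K+V-", "K-V+", "K-V-".
#' @export
categorize_kv <- function(kmi_score, vmi_score) {
  stopifnot(kmi_score >= 0, kmi_score <= 100, vmi_score >= 0, vmi_score <= 100)
  paste0(if (kmi_score >= 70) "K+" else "K-",
         if (vmi_score >= 70) "V+" else "V-")
}

#' Performance split at the cohort mean
#'
#' Subjects strictly above the cohort mean accuracy are "Perf+", the rest
#' "Perf-" (so a degenerate all-equal cohort is all Perf-).
#'
#' @param accuracies Numeric vector (>= 2 subjects).
#' @return Character vector of "Perf+"/"Perf-".
#' @export
split_perf <- function(accuracies) {
  stopifnot(length(accuracies) >= 2)
  ifelse(accuracies > mean(accuracies), "Perf+", "Perf-")
}

#' Manual-activity split
#'
#' Frequency ratings are ordinal 0..5 with anchors 0 = never, 1 = annually,
#' 2 = monthly, 3 = weekly, 4 = daily (5 = several times daily). Subjects
#' practicing at least weekly are "Manual+", the rest "Manual-".
#'
#' @param freq_manual Integer ratings in 0..5.
#' @return Character vector of "Manual+"/"Manual-".
#' @export
split_manual <- function(freq_manual) {
  if (any(!freq_manual %in% 0:5))
    stop("unknown frequency level; expected ordinal 0..5 ",
         "(never, annually, monthly, weekly, daily, several times daily)")
  ifelse(freq_manual >= 3, "Manual+", "Manual-")
}

.stat_result <- function(statistic, estimate, p_value, n, ...) {
  c(list(statistic = statistic, estimate = unname(estimate),
         p_value = unname(p_value), n = n), list(...))
}

#' Correlation tests
#'
#' Pearson product-moment and Spearman rank correlation with two-sided
#' p-values (t approximation; Spearman uses average ranks for ties).
#'
#' @param x,y Numeric vectors, n >= 3, finite, non-constant.
#' @return List: `statistic`, `estimate` (r or rho), `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  .check_corr_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  .stat_result("pearson_r", ct$estimate, ct$p.value, length(x))
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(x, y) {
  .check_corr_input(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  .stat_result("spearman_rho", ct$estimate, ct$p.value, length(x))
}

.check_corr_input <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need aligned vectors with n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  if (stats::sd(x) == 0) stop("x is constant; correlation undefined")
  if (stats::sd(y) == 0) stop("y is constant; correlation undefined")
}

#' Two-group location tests and normality test
#'
#' `welch_t`: unequal-variance t-test with Satterthwaite degrees of freedom.
#' `mann_whitney_u`: Mann-Whitney U; exact enumeration when both groups have
#' <= 8 observations and no ties, otherwise the normal approximation with
#' tie correction. `shapiro_wilk`: Shapiro-Wilk normality test.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param x Numeric vector (n >= 3) for `shapiro_wilk`.
#' @return List: `statistic`, `estimate` (t / U / W), `p_value`, `n`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 observations")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  .stat_result("welch_t", tt$statistic, tt$p.value, c(length(a), length(b)),
               df = unname(tt$parameter))
}

#' @rdname welch_t
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("empty group")
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  .stat_result("mann_whitney_u", wt$statistic, wt$p.value,
               c(length(a), length(b)), exact = exact)
}

#' @rdname welch_t
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs >= 3 observations")
  st <- stats::shapiro.test(x)
  .stat_result("shapiro_wilk", st$statistic, st$p.value, length(x))
}

#' Glass's Delta effect size
#'
#' \eqn{\Delta = |mean(a) - mean(b)| / sd(control)} with the larger sample as
#' the control group (its SD is the denominator; n-1 denominator SD); ties in
#' group size go to the first argument.
#'
#' @param a,b Numeric vectors; the control group needs >= 2 observations and
#'   nonzero SD.
#' @return List: `statistic`, `estimate` (Delta), `p_value` (NA; Delta is an
#'   effect size), `n`, `control`.
#' @export
glass_delta <- function(a, b) {
  control <- if (length(b) > length(a)) "b" else "a"
  ctrl <- if (control == "a") a else b
  if (length(ctrl) < 2) stop("control group needs >= 2 observations")
  s <- stats::sd(ctrl)
  if (s == 0) stop("control group has zero standard deviation")
  .stat_result("glass_delta", abs(mean(a) - mean(b)) / s, NA_real_,
               c(length(a), length(b)), control = control)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the m p-values ascending and finds the largest k with
#' \eqn{p_{(k)} \le k q / m}; those k hypotheses are rejected. Returns the
#' rejection flags (in input order) and the realised threshold `k q / m`
#' (0 when nothing is rejected).
#'
#' @param p_values Numeric vector in [0, 1].
#' @param q Target false-discovery rate (default 0.20).
#' @return List `rejected` (logical), `threshold` (numeric).
#' @export
bh_adjust <- function(p_values, q = 0.20) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  ord <- order(p_values)
  crit <- seq_len(m) * q / m
  ok <- which(p_values[ord] <= crit)
  if (!length(ok)) return(list(rejected = rep(FALSE, m), threshold = 0))
  k <- max(ok)
  rejected <- rep(FALSE, m)
  rejected[ord[seq_len(k)]] <- TRUE
  list(rejected = rejected, threshold = k * q / m)
}

#' Accuracy-questionnaire correlation table
#'
#' For every classification method and every score / personal-factor column,
#' computes Pearson and Spearman correlations between per-subject accuracy
#' and that variable, with Benjamini-Hochberg adjustment applied per
#' declared test family (by default each method's set of variables is one
#' family, per correlation type).
#'
#' @param records Subject table (one row per subject).
#' @param accuracies Named list or data.frame: one numeric accuracy vector
#'   per method, aligned with `records` rows.
#' @param variables Character vector of column names of `records` (or of
#'   derived scores, see `add_scores`) to correlate against.
#' @param add_scores If TRUE (default), derive `kmi_score`/`vmi_score` (and
#'   subset scores) from the MIQ-RS answers and make them available as
#'   variables.
#' @param q FDR level for the BH adjustment (default 0.20).
#' @return data.frame with columns `method`, `variable`, `type` ("pearson"/
#'   "spearman"), `estimate`, `p_value`, `n`, `significant`,
#'   `adjusted_threshold`.
#' @export
run_correlation_table <- function(records, accuracies,
                                  variables = c("kmi_score", "vmi_score"),
                                  add_scores = TRUE, q = 0.20) {
  if (is.data.frame(accuracies)) accuracies <- as.list(accuracies)
  tab <- records
  if (add_scores) {
    sc <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
      as.data.frame(score_miq(records[i, ]))))
    tab <- cbind(tab, sc)
  }
  miss <- setdiff(variables, names(tab))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (meth in names(accuracies)) {
    acc <- accuracies[[meth]]
    stopifnot(length(acc) == nrow(tab))
    for (v in variables) {
      x <- as.numeric(tab[[v]])
      for (type in c("pearson", "spearman")) {
        res <- if (type == "pearson") pearson_r(acc, x) else spearman_rho(acc, x)
        rows[[length(rows) + 1]] <- data.frame(
          method = meth, variable = v, type = type,
          estimate = res$estimate, p_value = res$p_value, n = res$n[1])
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- FALSE
  out$adjusted_threshold <- 0
  for (meth in unique(out$method)) {
    for (type in c("pearson", "spearman")) {
      sel <- out$method == meth & out$type == type
      adj <- bh_adjust(out$p_value[sel], q = q)
      out$significant[sel] <- adj$rejected
      out$adjusted_threshold[sel] <- adj$threshold
    }
  }
  out
}
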