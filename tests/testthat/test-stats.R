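mk_record <- function(k, v) {
  r <- as.list(c(stats::setNames(k, paste0("K", 1:7)),
                 stats::setNames(v, paste0("V", 1:7))))
  r
}

test_that("MIQ-RS scoring rescales 1..7 means to 0..100", {
  expect_equal(score_miq(mk_record(rep(7, 7), rep(7, 7)))$kmi_score, 100)
  expect_equal(score_miq(mk_record(rep(1, 7), rep(1, 7)))$vmi_score, 0)
  # alternating answers: mean 25/7 -> (25/7 - 1)/6 * 100
  sc <- score_miq(mk_record(c(1, 7, 1, 7, 1, 7, 1), rep(4, 7)))
  expect_equal(sc$kmi_score, (25 / 7 - 1) / 6 * 100, tolerance = 1e-12)
  expect_equal(sc$vmi_score, 50)
  # subset scores rescale the same way over the declared items
  sc2 <- score_miq(mk_record(c(1, 7, 1, 7, 1, 7, 1), rep(4, 7)),
                   subsets = list(hand = c(2, 4, 6)))
  expect_equal(sc2$kmi_hand_score, 100)
  expect_error(score_miq(mk_record(c(8, rep(4, 6)), rep(4, 7))), "1..7")
  expect_error(score_miq(mk_record(c(NA, rep(4, 6)), rep(4, 7))), "missing")
})

test_that("group assignments follow their thresholds exactly", {
  expect_equal(categorize_kv(70, 70), "K+V+")
  expect_equal(categorize_kv(69.99, 100), "K-V+")
  expect_equal(categorize_kv(100, 69.99), "K+V-")
  expect_equal(categorize_kv(0, 0), "K-V-")

  expect_equal(split_perf(c(0.6, 0.8)), c("Perf-", "Perf+"))
  expect_equal(split_perf(rep(0.7, 5)), rep("Perf-", 5))
  set.seed(91)
  acc <- runif(35, 0.4, 1)
  g <- split_perf(acc)
  expect_equal(length(g), 35)
  expect_gt(mean(acc[g == "Perf+"]), mean(acc[g == "Perf-"]))

  expect_equal(split_manual(c(4, 3, 2, 1, 0, 5)),
               c("Manual+", "Manual+", "Manual-", "Manual-", "Manual-", "Manual+"))
  expect_error(split_manual(7), "unknown frequency level")
})

test_that("correlation tests match direct-formula oracles", {
  x <- 1:10
  r <- pearson_r(x, 2 * x + 1)
  expect_equal(r$estimate, 1)
  expect_lt(r$p_value, 1e-6)

  y <- exp(x)                                # monotone nonlinear
  expect_equal(spearman_rho(x, y)$estimate, 1)
  expect_lt(pearson_r(x, y)$estimate, 1)

  set.seed(92)
  a <- rnorm(15); b <- 0.4 * a + rnorm(15)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$estimate, r_oracle, tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("Welch, Mann-Whitney and Shapiro-Wilk match their oracles", {
  g <- c(1, 2, 3, 4)
  w0 <- welch_t(g, g)
  expect_equal(w0$estimate, 0)
  expect_equal(w0$p_value, 1)

  # hand-computed Welch t and Satterthwaite df
  set.seed(93)
  a <- rnorm(5, 0, 1); b <- rnorm(50, 1, 10)
  se2a <- var(a) / 5; se2b <- var(b) / 50
  t_oracle <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_oracle <- (se2a + se2b)^2 / (se2a^2 / 4 + se2b^2 / 49)
  w <- welch_t(a, b)
  expect_equal(w$estimate, t_oracle, tolerance = 1e-10)
  expect_equal(w$df, df_oracle, tolerance = 1e-10)
  expect_equal(w$p_value, 2 * pt(-abs(t_oracle), df_oracle), tolerance = 1e-10)

  # complete separation, n1 = n2 = 3: U = 0, exact two-sided p from the
  # exhaustive permutation distribution over C(6,3) = 20 arrangements
  u <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$estimate, 0)
  pool <- c(1, 2, 3, 4, 5, 6)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- combn(6, 3)
  u_null <- apply(combos, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  u_obs <- u_stat(c(1, 2, 3), c(4, 5, 6))
  p_exact <- mean(pmin(u_null, 9 - u_null) <= min(u_obs, 9 - u_obs))
  expect_equal(p_exact, 0.1)
  expect_equal(u$p_value, p_exact, tolerance = 1e-12)
  expect_true(u$exact)

  # larger samples fall back to the normal approximation
  set.seed(94)
  u2 <- mann_whitney_u(rnorm(20), rnorm(20, 1))
  expect_false(u2$exact)

  sw <- shapiro_wilk(rnorm(30))
  expect_true(sw$p_value >= 0 && sw$p_value <= 1)
  expect_error(shapiro_wilk(c(1, 2)), ">= 3")
})

test_that("Glass's Delta uses the larger sample as control", {
  expect_equal(glass_delta(c(1, 2, 3), c(1, 2, 3))$estimate, 0)
  # means 10 vs 12, control (larger group) SD forced to 4
  ctrl <- c(8, 16, 12, 8, 16, 12)            # mean 12
  ctrl <- (ctrl - mean(ctrl)) / sd(ctrl) * 4 + 12
  d <- glass_delta(c(10, 10), ctrl)
  expect_equal(d$estimate, 0.5, tolerance = 1e-12)
  expect_equal(d$control, "b")
  # swapping argument order leaves Delta unchanged
  expect_equal(glass_delta(ctrl, c(10, 10))$estimate, d$estimate)
  expect_error(glass_delta(c(1, 2), c(3, 3, 3)), "zero standard deviation")
})

test_that("Benjamini-Hochberg equals the step-up enumeration oracle", {
  bh_oracle <- function(p, q) {
    m <- length(p); ord <- order(p); rej <- rep(FALSE, m); thr <- 0
    for (k in m:1) {
      if (p[ord[k]] <= k * q / m) {
        rej[ord[1:k]] <- TRUE; thr <- k * q / m; break
      }
    }
    list(rejected = rej, threshold = thr)
  }

  expect_equal(bh_adjust(rep(1, 5)), list(rejected = rep(FALSE, 5), threshold = 0))
  r <- bh_adjust(c(0.01, 0.02, 0.5, 0.9), q = 0.20)
  expect_equal(r$rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$threshold, 2 * 0.20 / 4)
  expect_true(bh_adjust(0.04, q = 0.05)$rejected)
  expect_false(bh_adjust(0.06, q = 0.05)$rejected)

  set.seed(95)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))^2
    q <- sample(c(0.05, 0.1, 0.2), 1)
    got <- bh_adjust(p, q)
    want <- bh_oracle(p, q)
    expect_equal(got, want)
    expect_equal(got$rejected, p.adjust(p, "BH") <= q)
    # monotonicity: lowering q never adds rejections
    expect_true(all(bh_adjust(p, q / 2)$rejected <= got$rejected))
  }
})

test_that("the correlation table is complete, consistent and BH-adjusted", {
  profs <- generate_profiles(sim_config(n_subjects = 35, seed = 96))
  rec <- profs$records
  rec$dup_factor <- rec$freq_manual          # duplicated column
  set.seed(96)
  acc <- list(tslr = surrogate_accuracy(profs$ground_truth$erd_mu_depth),
              mdrm = surrogate_accuracy(profs$ground_truth$erd_mu_depth))
  tab <- run_correlation_table(rec, acc,
                               variables = c("kmi_score", "vmi_score",
                                             "freq_manual", "dup_factor"))
  expect_equal(nrow(tab), 2 * 4 * 2)         # methods x variables x types
  expect_true(all(abs(tab$estimate) <= 1))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  dup <- subset(tab, variable %in% c("freq_manual", "dup_factor") &
                     method == "tslr" & type == "pearson")
  expect_equal(dup$estimate[1], dup$estimate[2], tolerance = 1e-12)
  # significance flags reproduce a direct BH pass over each family
  fam <- subset(tab, method == "tslr" & type == "pearson")
  expect_equal(fam$significant, bh_adjust(fam$p_value, 0.2)$rejected)
})
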