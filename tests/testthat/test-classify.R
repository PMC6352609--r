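test_that("per-trial covariances are SPD with the expected scale", {
  set.seed(81)
  ep <- gaussian_epochs(list(a = diag(6), b = diag(6)), 4, T_ = 896)
  cs <- compute_covariances(ep)
  expect_length(cs$covs, 8)
  expect_true(all(vapply(cs$covs, is_spd, TRUE)))
  # i.i.d. unit-variance noise at T = 896: diagonal near 1
  expect_true(all(abs(unlist(lapply(cs$covs, diag)) - 1) < 0.15))

  # duplicated channel rows: rank-deficient raw covariance, regularised SPD
  dup <- gaussian_epochs(list(a = diag(3)), 2, T_ = 100)
  dup$data[, 3, ] <- dup$data[, 2, ]
  cs2 <- compute_covariances(dup)
  expect_true(all(vapply(cs2$covs, is_spd, TRUE)))

  zero <- gaussian_epochs(list(a = diag(2)), 2, T_ = 50)
  zero$data[2, , ] <- 0
  expect_error(compute_covariances(zero), "trial 2")
})

test_that("CSP solves the class-variance eigenproblem", {
  # 2-channel toy: classes differ only in channel 1 variance; the analytic
  # generalised eigenvectors of (S1, S1+S2) are the coordinate axes
  S1 <- diag(c(9, 1)); S2 <- diag(c(1, 1))
  cs <- cov_set_of(list(S1, S1, S2, S2), c("a", "a", "b", "b"))
  mdl <- csp_fit(cs, n_filters = 2)
  w_top <- mdl$W[1, ]
  expect_gte(w_top[1]^2 / sum(w_top^2), 0.9)
  expect_equal(mdl$eigenvalues[1], 0.9, tolerance = 1e-10)  # 9/(9+1)

  # default F = 8 features, 80 vectors per session
  set.seed(82)
  ep <- gaussian_epochs(list(KMI = diag(c(4, rep(1, 11))), REST = diag(12)),
                        40, T_ = 200)
  cs12 <- compute_covariances(ep)
  f <- csp_features(csp_fit(cs12), ep)
  expect_equal(dim(f), c(80, 8))

  # identical class covariances: eigenvalues all 1/2, downstream near chance
  same <- cov_set_of(lapply(1:8, function(i) diag(3)), rep(c("a", "b"), 4))
  mdl0 <- csp_fit(same, n_filters = 2)
  expect_equal(mdl0$eigenvalues, rep(0.5, 2), tolerance = 1e-8)

  expect_error(csp_fit(same, n_filters = 4), "exceeds")
  expect_error(csp_fit(same, n_filters = 3), "even")
})

test_that("LDA behaves like a Fisher discriminant with equal priors", {
  # symmetric 1-D Gaussians: decision threshold at 0
  set.seed(83)
  x <- matrix(c(rnorm(200, -1), rnorm(200, 1)))
  y <- rep(c("neg", "pos"), each = 200)
  mdl <- lda_fit(x, y)
  expect_equal(lda_predict(mdl, matrix(c(-0.2, 0.2))), c("neg", "pos"))

  # linearly separable 4-point toy
  xs <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
  ys <- c("a", "a", "b", "b")
  expect_equal(lda_predict(lda_fit(xs, ys), xs), ys)

  # accuracy approaches the Bayes rate for known Gaussian classes
  bayes <- pnorm(1)                          # means +/-1, sd 1 -> 0.841
  set.seed(84)
  xtr <- matrix(c(rnorm(1000, -1), rnorm(1000, 1)))
  ytr <- rep(c("a", "b"), each = 1000)
  xte <- matrix(c(rnorm(1000, -1), rnorm(1000, 1)))
  yte <- rep(c("a", "b"), each = 1000)
  acc <- mean(lda_predict(lda_fit(xtr, ytr), xte) == yte)
  expect_lt(abs(acc - bayes), 0.03)

  expect_error(lda_fit(x, rep("one", 400)), "two classes")
})

test_that("MDRM equals the brute-force distance-comparison oracle", {
  set.seed(85)
  tr <- c(lapply(1:6, function(i) random_spd(3)),
          lapply(1:6, function(i) random_spd(3) * 2))
  labs <- rep(c("a", "b"), each = 6)
  mdl <- mdrm_fit(cov_set_of(tr, labs))
  test_mats <- lapply(1:50, function(i) random_spd(3, scale = runif(1, 0.5, 3)))
  pred <- mdrm_predict(mdl, test_mats)
  ma <- frechet_mean(tr[1:6]); mb <- frechet_mean(tr[7:12])
  oracle <- vapply(test_mats, function(m) {
    if (airm_distance(ma, m) <= airm_distance(mb, m)) "a" else "b"
  }, "")
  expect_identical(pred, oracle)

  # test matrix equal to a class mean classifies to that class
  expect_equal(mdrm_predict(mdl, list(ma, mb)), c("a", "b"))

  # single training matrix per class -> nearest-neighbour behaviour
  nn <- mdrm_fit(cov_set_of(list(diag(2), 4 * diag(2)), c("lo", "hi")))
  expect_equal(nn$means[[1]], diag(2))
  expect_equal(mdrm_predict(nn, list(1.1 * diag(2), 3 * diag(2))), c("lo", "hi"))
})

test_that("gfMDRM reduces to MDRM at full filter dimension and separates", {
  set.seed(86)
  covs <- c(lapply(1:8, function(i) regularize_spd(random_spd(3))),
            lapply(1:8, function(i) regularize_spd(random_spd(3) * 1.5)))
  labs <- rep(c("a", "b"), each = 8)
  cs <- cov_set_of(covs, labs)
  full <- gfmdrm_fit(cs, d = 6)
  plain <- mdrm_fit(cs)
  test_mats <- lapply(1:20, function(i) random_spd(3))
  expect_identical(gfmdrm_predict(full, test_mats), mdrm_predict(plain, test_mats))

  sep <- c(lapply(1:6, function(i) diag(c(exp(1), 1, 1)) + 0.01 * random_spd(3)),
           lapply(1:6, function(i) diag(c(exp(-1), 1, 1)) + 0.01 * random_spd(3)))
  labs2 <- rep(c("hi", "lo"), each = 6)
  mdl <- suppressWarnings(gfmdrm_fit(cov_set_of(sep, labs2)))
  expect_equal(gfmdrm_predict(mdl, sep), labs2)
})

test_that("TS+LR separates tangent clusters and respects AIRM invariance", {
  set.seed(87)
  mk <- function(n, shift) lapply(1:n, function(i)
    tangent_retract(diag(4), diag(c(shift + rnorm(1, 0, 0.1), 0, 0, 0)) +
                              0.05 * {e <- matrix(rnorm(16), 4); (e + t(e)) / 2}))
  covs <- c(mk(10, -1), mk(10, 1))
  labs <- rep(c("a", "b"), each = 10)
  mdl <- tslr_fit(cov_set_of(covs, labs))
  expect_equal(tslr_predict(mdl, covs), labs)

  # congruence-transforming every matrix by a fixed G leaves predictions
  # unchanged (tangent features rotate orthogonally; ridge is rotation-invariant)
  G <- matrix(rnorm(16), 4) + 2 * diag(4)
  covs_g <- lapply(covs, function(m) G %*% m %*% t(G))
  mdl_g <- tslr_fit(cov_set_of(covs_g, labs))
  expect_identical(tslr_predict(mdl_g, covs_g), tslr_predict(mdl, covs))

  # least-squares variant also separates the easy case
  mdl_ols <- tslr_fit(cov_set_of(covs, labs), classifier = "ols")
  expect_equal(tslr_predict(mdl_ols, covs), labs)
})

test_that("cross-validation partitions correctly and never leaks", {
  set.seed(88)
  ep <- gaussian_epochs(list(KMI = diag(c(6, 1, 1, 1)), REST = diag(4)),
                        40, T_ = 150)
  cv <- crossval_accuracy(ep, "mdrm", k = 4, seed = 42)
  expect_equal(cv$folds$n_test, rep(20L, 4))
  expect_equal(sum(cv$folds$n_test), 80)
  expect_gte(cv$mean, cv$min)
  expect_lte(cv$mean, cv$max)
  expect_gt(cv$mean, 0.9)                     # strongly separable construction

  # identical call -> identical folds and accuracies
  cv2 <- crossval_accuracy(ep, "mdrm", k = 4, seed = 42)
  expect_identical(cv$folds, cv2$folds)

  # chance level on shuffled labels, averaged over 20 shuffles
  accs <- vapply(1:20, function(s) {
    set.seed(200 + s)
    ep_s <- ep
    ep_s$labels <- sample(ep$labels)
    crossval_accuracy(ep_s, "mdrm", k = 4, seed = 42)$mean
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.08)

  # no information leak: altering one test trial leaves predictions for the
  # other test trials unchanged
  covset <- compute_covariances(ep)
  train <- 1:60; test <- 61:80
  p1 <- kmibci:::.fit_predict("mdrm", ep, covset, train, test)
  covset2 <- covset
  covset2$covs[[80]] <- covset2$covs[[80]] * 50
  p2 <- kmibci:::.fit_predict("mdrm", ep, covset2, train, test)
  expect_identical(p1[1:19], p2[1:19])

  expect_error(crossval_accuracy(gaussian_epochs(list(a = diag(2), b = diag(2)),
                                                 3, T_ = 50), "mdrm", k = 4),
               "at least k")
})
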