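#' Per-trial spatial covariance matrices
#'
#' For each epoch X (C x T, channel-mean-centred), the sample spatial
#' covariance \eqn{\Sigma_i = X_i X_i^\top / (T - 1)}, regularised to SPD if
#' numerically rank-deficient (eps = 1e-10 trace/C on the diagonal).
#'
#' @param epochs An `epoch_set`.
#' @return Object of class `cov_set`: list with `covs` (list of C x C SPD
#'   matrices) and `labels`.
#' @export
compute_covariances <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1]
  covs <- vector("list", n)
  for (i in seq_len(n)) {
    X <- epochs$data[i, , ]
    if (all(X == 0)) stop("trial ", i, " is all-zero; cannot form a covariance")
    X <- X - rowMeans(X)
    covs[[i]] <- regularize_spd(tcrossprod(X) / (ncol(X) - 1))
  }
  structure(list(covs = covs, labels = as.character(epochs$labels)),
            class = "cov_set")
}

.class_mean_cov <- function(covset, class) {
  sel <- covset$covs[covset$labels == class]
  .sym(Reduce(`+`, sel) / length(sel))
}

#' Common spatial patterns
#'
#' Fits spatial filters W (F x C) from the two class-average covariances by
#' the generalised eigenproblem \eqn{\bar\Sigma_1 w = \lambda (\bar\Sigma_1 +
#' \bar\Sigma_2) w}, eigenvalues sorted descending; the retained F filters
#' are the first and last F/2 (default 4 + 4). Ties in the eigenvalue order
#' are broken by the ascending channel index of each filter's dominant
#' coefficient, for determinism.
#'
#' @param covset A `cov_set` with two classes (training trials only).
#' @param n_filters Total retained filters F (even, <= C; default 8).
#' @return Object of class `csp_model` with `W`, `classes`, `eigenvalues`.
#' @export
csp_fit <- function(covset, n_filters = 8) {
  classes <- unique(covset$labels)
  if (length(classes) != 2) stop("CSP requires exactly two classes")
  S1 <- .class_mean_cov(covset, classes[1])
  S2 <- .class_mean_cov(covset, classes[2])
  C <- nrow(S1)
  if (n_filters %% 2 != 0) stop("n_filters must be even")
  if (n_filters > C) stop("n_filters exceeds the number of channels")
  Wht <- spd_power(regularize_spd(S1 + S2), -0.5)
  M <- .sym(Wht %*% S1 %*% Wht)
  e <- eigen(M, symmetric = TRUE)
  ord <- order(-e$values, apply(abs(e$vectors), 2, which.max))
  W <- t(e$vectors[, ord]) %*% Wht           # C x C bank, rows = filters
  keep <- c(seq_len(n_filters / 2), C - rev(seq_len(n_filters / 2)) + 1)
  structure(list(W = W[keep, , drop = FALSE], classes = classes,
                 eigenvalues = e$values[ord][keep]),
            class = "csp_model")
}

#' @rdname csp_fit
#' @param model A `csp_model`.
#' @param epochs An `epoch_set` to featurise.
#' @return `csp_features`: trials x F matrix of log-variances of the
#'   spatially filtered signals.
#' @export
csp_features <- function(model, epochs) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1]
  feats <- matrix(0, n, nrow(model$W))
  for (i in seq_len(n)) {
    X <- epochs$data[i, , ]
    X <- X - rowMeans(X)
    Y <- model$W %*% X
    feats[i, ] <- log(apply(Y, 1, stats::var))
  }
  feats
}

#' Fisher linear discriminant with equal priors
#'
#' Thin wrapper over [MASS::lda()] with equal class priors; falls back to a
#' direct ridge-regularised Fisher discriminant if the pooled covariance is
#' singular.
#'
#' @param features n x p feature matrix (training).
#' @param labels Two-class labels.
#' @return Object of class `lda_model`.
#' @export
lda_fit <- function(features, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("LDA requires exactly two classes in training")
  fit <- tryCatch(
    MASS::lda(features, grouping = factor(labels, levels = classes),
              prior = c(0.5, 0.5)),
    error = function(e) NULL)
  if (!is.null(fit))
    return(structure(list(engine = "mass", fit = fit, classes = classes),
                     class = "lda_model"))
  # ridge fallback: pooled covariance + small diagonal load
  m1 <- colMeans(features[labels == classes[1], , drop = FALSE])
  m2 <- colMeans(features[labels == classes[2], , drop = FALSE])
  Xc <- features
  Xc[labels == classes[1], ] <- sweep(features[labels == classes[1], , drop = FALSE], 2, m1)
  Xc[labels == classes[2], ] <- sweep(features[labels == classes[2], , drop = FALSE], 2, m2)
  Sp <- crossprod(Xc) / max(1, nrow(features) - 2)
  Sp <- Sp + diag(1e-6 * mean(diag(Sp)) + 1e-12, ncol(features))
  w <- solve(Sp, m1 - m2)
  b <- sum(w * (m1 + m2) / 2)
  structure(list(engine = "ridge", w = w, b = b, classes = classes),
            class = "lda_model")
}

#' @rdname lda_fit
#' @param model An `lda_model`.
#' @return `lda_predict`: character vector of predicted labels.
#' @export
lda_predict <- function(model, features) {
  stopifnot(inherits(model, "lda_model"))
  if (model$engine == "mass")
    return(as.character(stats::predict(model$fit, features)$class))
  scores <- drop(features %*% model$w) - model$b
  ifelse(scores >= 0, model$classes[1], model$classes[2])
}

#' Minimum distance to Riemannian mean (MDRM)
#'
#' Each class is summarised by the Fréchet mean of its training covariance
#' matrices; a trial is assigned to the class whose mean is nearest in AIRM
#' distance. Ties go to the first class in the fixed label order.
#'
#' @param covset Training `cov_set`.
#' @return Object of class `mdrm_model` (`means`, `classes`).
#' @export
mdrm_fit <- function(covset) {
  classes <- unique(covset$labels)
  if (length(classes) != 2) stop("MDRM requires exactly two classes")
  means <- lapply(classes, function(cl) frechet_mean(covset$covs[covset$labels == cl]))
  structure(list(means = means, classes = classes), class = "mdrm_model")
}

#' @rdname mdrm_fit
#' @param model An `mdrm_model`.
#' @param covs List of SPD matrices to classify.
#' @return `mdrm_predict`: character vector of predicted labels.
#' @export
mdrm_predict <- function(model, covs) {
  stopifnot(inherits(model, "mdrm_model"))
  vapply(covs, function(m) {
    d <- vapply(model$means, airm_distance, 0, b = m)
    model$classes[which.min(d)]             # which.min takes the first on ties
  }, "")
}

#' Geodesically filtered MDRM (gfMDRM)
#'
#' [geodesic_filter()] is fitted on the training matrices only, both training
#' and test matrices are filtered, and MDRM is applied to the filtered set.
#'
#' @param covset Training `cov_set`.
#' @param d Discriminant dimension of the filter (default 1).
#' @return Object of class `gfmdrm_model`.
#' @export
gfmdrm_fit <- function(covset, d = 1) {
  gf <- geodesic_filter(covset$covs, covset$labels, d = d)
  filtered <- gf_transform(gf, covset$covs)
  mdrm <- mdrm_fit(structure(list(covs = filtered, labels = covset$labels),
                             class = "cov_set"))
  structure(list(filter = gf, mdrm = mdrm), class = "gfmdrm_model")
}

#' @rdname gfmdrm_fit
#' @param model A `gfmdrm_model`.
#' @param covs List of SPD matrices to classify.
#' @export
gfmdrm_predict <- function(model, covs) {
  stopifnot(inherits(model, "gfmdrm_model"))
  mdrm_predict(model$mdrm, gf_transform(model$filter, covs))
}

#' Tangent-space linear classifier (TS+LR)
#'
#' Covariance matrices are projected onto the tangent space at the Fréchet
#' mean of the training set — the point where the tangent space best
#' approximates the manifold — vectorised isometrically, and classified with
#' an L2-regularised logistic regression (threshold 0.5). A plain
#' least-squares variant (`classifier = "ols"`: ridge regression on 0/1
#' targets with a vanishing penalty, threshold 0.5) is kept for fidelity
#' comparisons with a literal linear-regression reading.
#'
#' @param covset Training `cov_set`.
#' @param classifier "logistic" (default) or "ols".
#' @param lambda Ridge penalty; default 1/n for the logistic engine.
#' @return Object of class `tslr_model`.
#' @export
tslr_fit <- function(covset, classifier = c("logistic", "ols"), lambda = NULL) {
  classifier <- match.arg(classifier)
  classes <- unique(covset$labels)
  if (length(classes) != 2) stop("TS+LR requires exactly two classes")
  if (any(table(covset$labels) < 2)) stop("need >= 2 training matrices per class")
  base <- frechet_mean(covset$covs)
  V <- t(vapply(covset$covs,
                function(m) tangent_vectorize(tangent_map(base, m)),
                numeric(nrow(base) * (nrow(base) + 1) / 2)))
  y <- as.integer(covset$labels == classes[2])
  n <- nrow(V)
  if (is.null(lambda)) lambda <- if (classifier == "logistic") 1 / n else 1e-8
  fam <- if (classifier == "logistic") "binomial" else "gaussian"
  fit <- glmnet::glmnet(V, y, family = fam, alpha = 0, lambda = lambda,
                        standardize = FALSE)
  structure(list(base = base, fit = fit, classes = classes,
                 classifier = classifier),
            class = "tslr_model")
}

#' @rdname tslr_fit
#' @param model A `tslr_model`.
#' @param covs List of SPD matrices to classify.
#' @export
tslr_predict <- function(model, covs) {
  stopifnot(inherits(model, "tslr_model"))
  V <- t(vapply(covs,
                function(m) tangent_vectorize(tangent_map(model$base, m)),
                numeric(nrow(model$base) * (nrow(model$base) + 1) / 2)))
  p <- drop(stats::predict(model$fit, V, type = "response"))
  ifelse(p >= 0.5, model$classes[2], model$classes[1])
}

.fit_predict <- function(method, epochs, covset, train, test, gf_d = 1) {
  tr_cov <- structure(list(covs = covset$covs[train], labels = covset$labels[train]),
                      class = "cov_set")
  switch(method,
    csp_lda = {
      tr_ep <- epoch_set(epochs$data[train, , , drop = FALSE],
                         epochs$labels[train], epochs$fs, epochs$channel_labels)
      te_ep <- epoch_set(epochs$data[test, , , drop = FALSE],
                         epochs$labels[test], epochs$fs, epochs$channel_labels)
      csp <- csp_fit(tr_cov)
      lda <- lda_fit(csp_features(csp, tr_ep), epochs$labels[train])
      lda_predict(lda, csp_features(csp, te_ep))
    },
    mdrm = mdrm_predict(mdrm_fit(tr_cov), covset$covs[test]),
    gfmdrm = gfmdrm_predict(gfmdrm_fit(tr_cov, d = gf_d), covset$covs[test]),
    tslr = tslr_predict(tslr_fit(tr_cov), covset$covs[test]),
    stop("unknown method: ", method))
}

#' Cross-validated decoding accuracy
#'
#' Evaluates one of the four classifiers (CSP+LDA, MDRM, gfMDRM, TS+LR)
#' under k-fold cross-validation. Folds are stratified by class by default
#' (chronological blocks within class available via `stratified = FALSE`,
#' which partitions trials in recording order); all fitting — CSP filters,
#' Fréchet means, geodesic filters, classifier weights — happens inside the
#' training folds only.
#'
#' @param epochs An `epoch_set`.
#' @param method One of "csp_lda", "mdrm", "gfmdrm", "tslr".
#' @param k Number of folds (default 4); every class must have >= k trials.
#' @param seed Seed for the fold shuffle (default 42).
#' @param stratified Stratify folds by class (default TRUE).
#' @return List with `folds` (data.frame: fold, n_test, n_correct,
#'   accuracy), `mean` (trial-weighted mean accuracy), `min`, `max`.
#' @export
crossval_accuracy <- function(epochs,
                              method = c("csp_lda", "mdrm", "gfmdrm", "tslr"),
                              k = 4, seed = 42, stratified = TRUE) {
  method <- match.arg(method)
  labels <- as.character(epochs$labels)
  n <- length(labels)
  if (any(table(labels) < k))
    stop("every class needs at least k = ", k, " trials")
  fold_of <- .assign_folds(labels, k, seed, stratified)
  covset <- compute_covariances(epochs)
  res <- data.frame(fold = seq_len(k), n_test = 0L, n_correct = 0L, accuracy = 0)
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    pred <- .fit_predict(method, epochs, covset, train, test)
    res$n_test[f] <- length(test)
    res$n_correct[f] <- sum(pred == labels[test])
    res$accuracy[f] <- res$n_correct[f] / res$n_test[f]
  }
  list(folds = res,
       mean = sum(res$n_correct) / sum(res$n_test),
       min = min(res$accuracy), max = max(res$accuracy))
}

.assign_folds <- function(labels, k, seed, stratified) {
  n <- length(labels)
  fold_of <- integer(n)
  if (stratified) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  } else {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_of[idx] <- as.integer(cut(seq_along(idx), k, labels = FALSE))
    }
  }
  fold_of
}
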