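#' @name riemann
#' @title Geometry of symmetric positive-definite matrices
#' @description
#' The spatial covariance matrix of an EEG epoch is symmetric
#' positive-definite (SPD); the set of SPD matrices forms a Riemannian
#' manifold under the affine-invariant metric (AIRM), whose distance
#' \deqn{\delta(A,B) = \|\log(A^{-1/2} B A^{-1/2})\|_F}
#' is invariant under congruence transformations \eqn{\Sigma \mapsto G
#' \Sigma G^\top} — i.e. under any linear mixing of the channels. All matrix
#' logarithms/exponentials are computed by eigendecomposition of the
#' symmetrised argument.
NULL

.sym <- function(x) (x + t(x)) / 2

#' Test / enforce symmetric positive-definiteness
#'
#' @param x Square numeric matrix.
#' @param tol Symmetry tolerance (absolute, default 1e-10 relative to scale).
#' @return `is_spd`: logical. `regularize_spd`: `x` with `eps * I` added
#'   (eps = 1e-10 trace/C) when the smallest eigenvalue is not positive.
#' @export
is_spd <- function(x, tol = 1e-10) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) return(FALSE)
  if (max(abs(x - t(x))) > tol * max(1, max(abs(x)))) return(FALSE)
  min(eigen(.sym(x), symmetric = TRUE, only.values = TRUE)$values) > 0
}

#' @rdname is_spd
#' @export
regularize_spd <- function(x) {
  x <- .sym(x)
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    eps <- 1e-10 * sum(diag(x)) / nrow(x)
    shift <- abs(min(ev)) + max(eps, .Machine$double.eps * sum(diag(x)))
    x <- x + diag(shift, nrow(x))
  }
  x
}

.assert_spd <- function(x, what = "matrix") {
  if (!is_spd(x)) stop(what, " is not symmetric positive-definite")
  invisible(x)
}

# U f(lambda) U' of a symmetric matrix
.spd_fun <- function(x, f) {
  e <- eigen(.sym(x), symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

#' Matrix power, log and exp on SPD / symmetric matrices
#'
#' @param x SPD matrix (`spd_power`, `spd_logm`) or symmetric matrix
#'   (`spd_expm`).
#' @param p Exponent.
#' @return Matrix of the same dimension.
#' @export
spd_power <- function(x, p) .spd_fun(.assert_spd(x), function(l) l^p)

#' @rdname spd_power
#' @export
spd_logm <- function(x) .spd_fun(.assert_spd(x), log)

#' @rdname spd_power
#' @export
spd_expm <- function(x) .spd_fun(x, exp)

#' Affine-invariant Riemannian distance
#'
#' @param a,b SPD matrices of equal dimension.
#' @return Nonnegative scalar; 0 iff `a == b`; symmetric in its arguments
#'   and invariant under `a, b -> G a G', G b G'`.
#' @export
airm_distance <- function(a, b) {
  .assert_spd(a, "first argument"); .assert_spd(b, "second argument")
  s <- spd_power(a, -0.5)
  lam <- eigen(.sym(s %*% b %*% s), symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Fréchet (Karcher) mean of SPD matrices
#'
#' Fixed point of the Riemannian gradient-descent iteration
#' \eqn{M \leftarrow M^{1/2} \exp(\mathrm{mean}_i \log(M^{-1/2} \Sigma_i
#' M^{-1/2})) M^{1/2}}, initialised at the arithmetic mean with unit step.
#'
#' @param mats List of SPD matrices (>= 1).
#' @param tol Convergence tolerance on the Frobenius norm of the mean
#'   tangent vector.
#' @param max_iter Maximum iterations; non-convergence is an error reporting
#'   the last gradient norm.
#' @return The SPD mean matrix.
#' @export
frechet_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  stopifnot(length(mats) >= 1)
  for (m in mats) .assert_spd(m)
  if (length(mats) == 1) return(mats[[1]])
  M <- .sym(Reduce(`+`, mats) / length(mats))
  for (it in seq_len(max_iter)) {
    Ms <- .spd_fun(M, sqrt)
    Mis <- .spd_fun(M, function(l) 1 / sqrt(l))
    S <- matrix(0, nrow(M), ncol(M))
    for (m in mats) S <- S + .spd_fun(Mis %*% m %*% Mis, log)
    S <- S / length(mats)
    g <- sqrt(sum(S^2))
    if (g <= tol) return(.sym(M))
    M <- .sym(Ms %*% .spd_fun(S, exp) %*% Ms)
  }
  stop(sprintf("Frechet mean did not converge in %d iterations (gradient norm %.3e)",
               max_iter, g))
}

#' Tangent-space log map and retraction
#'
#' `tangent_map` sends an SPD matrix to the tangent space at `base`:
#' \eqn{S = \log(B^{-1/2} X B^{-1/2})}; `tangent_retract` is its inverse.
#' The Frobenius norm of the tangent vector equals the AIRM distance from
#' the base point.
#'
#' @param base SPD base point.
#' @param x SPD matrix to map.
#' @param s Symmetric tangent matrix to retract.
#' @return Symmetric matrix / SPD matrix.
#' @export
tangent_map <- function(base, x) {
  .assert_spd(base, "base point"); .assert_spd(x)
  bis <- spd_power(base, -0.5)
  .spd_fun(bis %*% x %*% bis, log)
}

#' @rdname tangent_map
#' @export
tangent_retract <- function(base, s) {
  bs <- spd_power(base, 0.5)
  .sym(bs %*% .spd_fun(s, exp) %*% bs)
}

#' Vectorise a symmetric matrix isometrically
#'
#' Upper triangle flattened with off-diagonal entries scaled by sqrt(2) so
#' the Euclidean norm of the vector equals the Frobenius norm of the matrix;
#' length C(C+1)/2 (528 for C = 32).
#'
#' @param s Symmetric matrix / numeric vector of length C(C+1)/2.
#' @return Numeric vector / symmetric matrix.
#' @export
tangent_vectorize <- function(s) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  ut <- upper.tri(s)
  c(diag(s), sqrt(2) * s[ut])
}

#' @rdname tangent_vectorize
#' @export
tangent_unvectorize <- function(v) {
  p <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(p - round(p)) > 1e-9) stop("vector length is not C(C+1)/2 for integer C")
  p <- round(p)
  s <- matrix(0, p, p)
  diag(s) <- v[seq_len(p)]
  s[upper.tri(s)] <- v[-seq_len(p)] / sqrt(2)
  s <- s + t(s) - diag(diag(s))
  s
}

#' Geodesic (tangent-space Fisher) filtering of covariance matrices
#'
#' A denoising step for minimum-distance classification: training matrices
#' are mapped to the tangent space at their global Fréchet mean, a
#' discriminant subspace of dimension `d` is fitted there by the Fisher
#' criterion (between- over within-class scatter), tangent vectors are
#' orthogonally projected onto that subspace and retracted back to the
#' manifold. With two classes the informative Fisher subspace has dimension
#' 1 (the default); `d` equal to the full tangent dimension makes the filter
#' the identity. A singular within-class scatter is ridge-regularised with a
#' warning.
#'
#' @param covs List of SPD training matrices.
#' @param labels Two-class label vector aligned with `covs`.
#' @param d Retained discriminant dimensions (default 1).
#' @return Object of class `geodesic_filter` with elements `base`,
#'   `projection` (p x p), `d`; apply with [gf_transform()].
#' @export
geodesic_filter <- function(covs, labels, d = 1) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("geodesic_filter requires exactly two classes")
  if (any(table(labels) < 2)) stop("need >= 2 matrices per class")
  base <- frechet_mean(covs)
  V <- t(vapply(covs, function(m) tangent_vectorize(tangent_map(base, m)),
                numeric(nrow(base) * (nrow(base) + 1) / 2)))
  p <- ncol(V)
  if (d >= p) {
    P <- diag(p)
  } else {
    m1 <- colMeans(V[labels == classes[1], , drop = FALSE])
    m2 <- colMeans(V[labels == classes[2], , drop = FALSE])
    Vc <- V
    Vc[labels == classes[1], ] <- sweep(V[labels == classes[1], , drop = FALSE], 2, m1)
    Vc[labels == classes[2], ] <- sweep(V[labels == classes[2], , drop = FALSE], 2, m2)
    Sw <- crossprod(Vc) / (nrow(V) - 2)
    ev_min <- min(eigen(Sw, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 1e-10 * sum(diag(Sw)) / p) {
      warning("singular within-class scatter; applying ridge regularisation")
      Sw <- Sw + diag(1e-3 * sum(diag(Sw)) / p, p)
    }
    if (d == 1) {
      B <- matrix(solve(Sw, m1 - m2), ncol = 1)
    } else {
      mg <- (m1 + m2) / 2
      Sb <- tcrossprod(m1 - mg) + tcrossprod(m2 - mg)
      e <- eigen(solve(Sw, Sb))
      B <- Re(e$vectors[, seq_len(d), drop = FALSE])
    }
    B <- qr.Q(qr(B))
    P <- tcrossprod(B)
  }
  structure(list(base = base, projection = P, d = d),
            class = "geodesic_filter")
}

#' Apply a fitted geodesic filter
#'
#' @param model A [geodesic_filter()] fit.
#' @param covs List of SPD matrices to filter.
#' @return List of filtered SPD matrices.
#' @export
gf_transform <- function(model, covs) {
  stopifnot(inherits(model, "geodesic_filter"))
  lapply(covs, function(m) {
    v <- tangent_vectorize(tangent_map(model$base, m))
    tangent_retract(model$base, tangent_unvectorize(drop(model$projection %*% v)))
  })
}
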