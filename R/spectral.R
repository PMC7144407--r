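# Finite-dimensional spectral machinery: singular systems of a forward matrix
# A, spectral functions of A*A, filter-based regularizers B_alpha, source
# elements (A*A)^mu omega and kernel projectors.

#' Singular system of a forward matrix
#'
#' Computes the full singular value decomposition `A = V diag(sigma) U'`
#' (in the inverse-problems convention: `A x = sum_n sigma_n <u_n, x> v_n`
#' with `u_n` in the image/domain space and `v_n` in the data space) and
#' wraps it in a `spectral_system` object used by every regularizer in the
#' package. Singular values at or below `rank_tol * sigma_1` are treated as
#' the numerical kernel of `A`.
#'
#' @param matrix Real matrix (dense or a `Matrix` sparse matrix), `m x d`.
#' @param rank_tol Relative threshold in `(0, 1)` separating the numerical
#'   kernel; default `1e-10`.
#' @return An object of class `spectral_system` with fields `matrix`,
#'   `singular_values` (length `min(m, d)`, non-increasing), `domain_basis`
#'   (`d x k` orthonormal columns `u_n`), `range_basis` (`m x k` orthonormal
#'   columns `v_n`), `rank_tol`, `m`, `d`.
#' @export
svd_decompose <- function(matrix, rank_tol = 1e-10) {
  if (inherits(matrix, "Matrix")) {
    dense <- as.matrix(matrix)
  } else {
    dense <- as.matrix(matrix)
  }
  if (!all(is.finite(dense))) {
    bad <- which(!is.finite(dense), arr.ind = TRUE)[1L, ]
    stop(sprintf("forward matrix has a non-finite entry at (%d, %d)", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (!is.numeric(rank_tol) || length(rank_tol) != 1L || rank_tol <= 0 || rank_tol >= 1) {
    stop("`rank_tol` must be a single number in (0, 1)", call. = FALSE)
  }
  sv <- svd(dense)
  sys <- structure(list(
    matrix = matrix,
    singular_values = sv$d,
    domain_basis = sv$v,   # u_n: image-space singular vectors
    range_basis = sv$u,    # v_n: data-space singular vectors
    rank_tol = rank_tol,
    m = nrow(dense),
    d = ncol(dense)
  ), class = "spectral_system")
  sys
}

#' Diagonal toy spectral system
#'
#' Builds the `spectral_system` of `diag(sigma)` directly (no numerical SVD),
#' with exact canonical singular vectors. Used throughout the theory
#' verification suites, where the paper-style model problems are diagonal.
#'
#' @param sigma Non-negative singular values (any order; sorted internally).
#' @param rank_tol Relative numerical-kernel threshold.
#' @return A `spectral_system`.
#' @export
diagonal_system <- function(sigma, rank_tol = 1e-10) {
  stopifnot(all(is.finite(sigma)), all(sigma >= 0))
  ord <- order(sigma, decreasing = TRUE)
  d <- length(sigma)
  basis <- diag(d)[, ord, drop = FALSE]
  structure(list(
    matrix = diag(sigma, nrow = d),
    singular_values = sigma[ord],
    domain_basis = basis,
    range_basis = basis,
    rank_tol = rank_tol,
    m = d,
    d = d
  ), class = "spectral_system")
}

#' @export
print.spectral_system <- function(x, ...) {
  sv <- x$singular_values
  cat(sprintf("<spectral_system> %d x %d, sigma_1 = %.4g, rank(tol=%.1g) = %d\n",
              x$m, x$d, sv[1L], x$rank_tol, sum(sv > x$rank_tol * sv[1L])))
  invisible(x)
}

# index mask of singular values above the numerical-kernel threshold
positive_mask <- function(system) {
  sv <- system$singular_values
  sv > system$rank_tol * sv[1L]
}

#' Apply the forward operator or its adjoint
#'
#' @param system A `spectral_system`.
#' @param x Domain vector of length `d` (`apply_forward`) or data vector of
#'   length `m` (`apply_adjoint`).
#' @return A plain numeric vector.
#' @export
apply_forward <- function(system, x) {
  stopifnot(length(x) == system$d)
  as.vector(system$matrix %*% x)
}

#' @rdname apply_forward
#' @export
apply_adjoint <- function(system, x) {
  stopifnot(length(x) == system$m)
  as.vector(Matrix::crossprod(system$matrix, x))
}

#' Spectral function of A*A applied to a vector
#'
#' Evaluates `f(A*A) x = sum_n f(sigma_n^2) <u_n, x> u_n + f(0) P_perp x`,
#' where `P_perp` projects onto the orthogonal complement of the stored
#' domain basis (part of the kernel when `d > m`).
#'
#' @param system A `spectral_system`.
#' @param f Scalar function, finite on `[0, sigma_1^2]`; vectorized over its
#'   argument.
#' @param x Domain vector of length `d`.
#' @return Domain vector `f(A*A) x`.
#' @export
apply_spectral_function <- function(system, f, x) {
  stopifnot(length(x) == system$d)
  lam <- system$singular_values^2
  fv <- f(lam)
  if (!all(is.finite(fv))) {
    bad <- lam[which(!is.finite(fv))[1L]]
    stop(sprintf("spectral function is non-finite at eigenvalue %.6g", bad),
         call. = FALSE)
  }
  f0 <- f(0)
  if (!is.finite(f0)) stop("spectral function is non-finite at eigenvalue 0", call. = FALSE)
  V <- system$domain_basis
  coef <- drop(crossprod(V, x))
  as.vector(V %*% (fv * coef)) + f0 * (x - as.vector(V %*% coef))
}

#' Filter-based regularized reconstruction B_alpha y
#'
#' Applies `B_alpha = g_alpha(A*A) A*`, i.e.
#' `B_alpha y = sum_n g_alpha(sigma_n^2) sigma_n <y, v_n> u_n`. For the
#' truncated-SVD filter this is exactly
#' `sum_{sigma_n^2 >= alpha} <y, v_n> u_n / sigma_n`.
#'
#' @param system A `spectral_system`.
#' @param filter A [filter_spec()].
#' @param alpha Positive regularization parameter.
#' @param y Data vector of length `m`.
#' @return Domain vector of length `d`, in the span of the positive-sigma
#'   domain basis.
#' @export
apply_regularizer <- function(system, filter, alpha, y) {
  stopifnot(inherits(filter, "filter_spec"), alpha > 0)
  if (length(y) != system$m) {
    stop(sprintf("data vector has length %d; expected m = %d", length(y), system$m),
         call. = FALSE)
  }
  sv <- system$singular_values
  g <- filter$g(sv^2, alpha)
  coef <- drop(crossprod(system$range_basis, y))
  as.vector(system$domain_basis %*% (g * sv * coef))
}

#' Operator norm of B_alpha
#'
#' `max_n |g_alpha(sigma_n^2) sigma_n|`, the spectral norm of the
#' regularizer on the discrete system.
#'
#' @inheritParams apply_regularizer
#' @return Non-negative scalar.
#' @export
regularizer_norm <- function(system, filter, alpha) {
  sv <- system$singular_values
  max(abs(filter$g(sv^2, alpha) * sv))
}

#' Source element (A*A)^mu omega
#'
#' `sum_n sigma_n^(2 mu) <u_n, omega> u_n`; for `mu > 0` the kernel component
#' of `omega` is annihilated, for `mu = 0` the identity is returned.
#'
#' @param system A `spectral_system`.
#' @param mu Non-negative smoothness order.
#' @param omega Domain vector of length `d`.
#' @return Domain vector.
#' @export
source_element <- function(system, mu, omega) {
  stopifnot(mu >= 0, length(omega) == system$d)
  if (mu == 0) return(omega)
  V <- system$domain_basis
  coef <- drop(crossprod(V, omega))
  as.vector(V %*% (system$singular_values^(2 * mu) * coef))
}

#' Orthogonal projection onto the numerical kernel of A
#'
#' Projects onto the span of domain-basis vectors with
#' `sigma_n <= rank_tol * sigma_1` together with the orthogonal complement of
#' all stored domain-basis vectors.
#'
#' @param system A `spectral_system`.
#' @param x Domain vector of length `d`.
#' @return Domain vector `P_ker(A) x`.
#' @export
kernel_projector <- function(system, x) {
  stopifnot(length(x) == system$d)
  pos <- positive_mask(system)
  Vp <- system$domain_basis[, pos, drop = FALSE]
  x - as.vector(Vp %*% crossprod(Vp, x))
}

#' Singular values only (for large operators)
#'
#' Convenience wrapper computing the singular values of a (possibly sparse)
#' matrix without accumulating singular vectors; used for the full-scale
#' Radon operator where only the spectrum is needed.
#'
#' @param matrix Real matrix, dense or sparse.
#' @return Non-increasing vector of singular values.
#' @export
operator_singular_values <- function(matrix) {
  svd(as.matrix(matrix), nu = 0, nv = 0)$d
}
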