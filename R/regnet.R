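# Reconstruction maps: plain filter regularization B_alpha, null-space
# networks (Id + P_ker U) B_alpha, and the data-driven continued SVD that
# fills the truncated singular components from the retained ones.

#' Construct a RegNet reconstruction model
#'
#' Bundles a spectral system, a regularizing filter, a regularization
#' parameter and (optionally) a trained network into a reconstruction map
#' `R_alpha = (Id + N_theta(alpha)) B_alpha`. The `mode` fixes how the
#' network output is projected:
#'
#' * `"plain"`: no network, `R_alpha = B_alpha`.
#' * `"continued_svd"` (truncated-SVD filter only): the network-added
#'   component lies in the orthogonal complement of the retained singular
#'   vectors (`sigma_n^2 >= alpha`), i.e. the truncated band together with
#'   the numerical kernel; retained coefficients are untouched.
#' * `"null_space"` (truncated-SVD filter only): the added component is
#'   projected onto the numerical kernel of `A` only, so it is invisible to
#'   the forward operator.
#'
#' @param system A `spectral_system`.
#' @param filter A [filter_spec()].
#' @param alpha Positive regularization parameter.
#' @param network A `network_function` (ignored for `mode = "plain"`).
#' @param mode One of `"plain"`, `"continued_svd"`, `"null_space"`.
#' @param band For `"continued_svd"`: `"complement"` (default; the full
#'   orthogonal complement of the retained vectors) or `"strict"` (only
#'   stored vectors with `0 < sigma_n^2 < alpha`).
#' @return An object of class `regnet_model`.
#' @export
regnet_model <- function(system, filter, alpha, network = NULL,
                         mode = c("plain", "continued_svd", "null_space"),
                         band = c("complement", "strict")) {
  mode <- match.arg(mode)
  band <- match.arg(band)
  stopifnot(inherits(system, "spectral_system"), inherits(filter, "filter_spec"),
            alpha > 0)
  if (mode != "plain") {
    if (filter$name != "tsvd") {
      stop(sprintf("mode '%s' requires the truncated-SVD filter, got '%s'",
                   mode, filter$name), call. = FALSE)
    }
    if (is.null(network)) stop("modes with a network require `network`", call. = FALSE)
    stopifnot(inherits(network, "network_function"))
  }
  structure(list(system = system, filter = filter, alpha = alpha,
                 network = network, mode = mode, band = band),
            class = "regnet_model")
}

#' @export
print.regnet_model <- function(x, ...) {
  cat(sprintf("<regnet_model> mode %s, %s filter, alpha = %g, %s\n",
              x$mode, x$filter$name, x$alpha,
              if (is.null(x$network)) "no network" else x$network$descriptor))
  invisible(x)
}

# projector basis for the mode's band: columns of the domain basis whose
# coefficients the network must NOT change
model_retained_basis <- function(model) {
  sys <- model$system
  sv <- sys$singular_values
  keep <- switch(model$mode,
    continued_svd = if (model$band == "complement") sv^2 >= model$alpha
                    else (sv^2 >= model$alpha | !positive_mask(sys)),
    null_space = positive_mask(sys),
    stop("no projector band for mode 'plain'", call. = FALSE)
  )
  sys$domain_basis[, keep, drop = FALSE]
}

# project a batch of network outputs onto the mode's band: complement of the
# retained basis (symmetric, idempotent); used by reconstruction and training
project_band <- function(model, Z) {
  Vr <- model_retained_basis(model)
  Z <- as.matrix(Z)
  Z - as.matrix(Vr %*% crossprod(Vr, Z))
}

#' Apply a null-space network N = P_ker(A) U
#'
#' Evaluates the network on `x` and projects the result onto the numerical
#' kernel of `A`, so the returned component satisfies
#' `|A out| <= rank_tol * sigma_1 * |U(x)|`.
#'
#' @param system A `spectral_system`.
#' @param network A `network_function`.
#' @param x Domain vector.
#' @return Domain vector in the numerical kernel of `A`.
#' @export
nullspace_network_apply <- function(system, network, x) {
  kernel_projector(system, network_apply(network, x))
}

# the additive correction N_theta(alpha)(b) applied to a regularized
# reconstruction b (d-vector or d x B matrix); zero for mode "plain"
regnet_correction <- function(model, b) {
  if (model$mode == "plain") return(b * 0)
  Z <- network_apply(model$network, b)
  if (is.null(dim(b))) drop(project_band(model, matrix(Z, ncol = 1L))) else
    project_band(model, Z)
}

#' Reconstruct from data with a RegNet
#'
#' Computes `b = B_alpha y` and returns `b + N_theta(alpha)(b)`, where the
#' network correction is determined by the model's mode (zero for
#' `"plain"`).
#'
#' @param model A [regnet_model()].
#' @param y Data vector of length `m`, or an `m x B` matrix of columns.
#' @return Domain vector (or `d x B` matrix) of coefficients.
#' @export
regnet_reconstruct <- function(model, y) {
  sys <- model$system
  if (is.null(dim(y))) {
    b <- apply_regularizer(sys, model$filter, model$alpha, y)
    if (model$mode == "plain") return(b)
    b + regnet_correction(model, b)
  } else {
    stopifnot(nrow(y) == sys$m)
    b <- filter_inputs(sys, model$filter, model$alpha, y)
    if (model$mode == "plain") return(b)
    b + regnet_correction(model, b)
  }
}

#' Data-driven continued SVD reconstruction
#'
#' Truncated SVD whose discarded components are filled in by the trained
#' network: retained coefficients (`sigma_n^2 >= alpha`) equal those of
#' `B_alpha y` exactly; coefficients in the truncated band are read off the
#' network output `U_theta(B_alpha y)`.
#'
#' @param model A [regnet_model()] with `mode = "continued_svd"`.
#' @param y Data vector.
#' @return Domain vector.
#' @export
continued_svd_reconstruct <- function(model, y) {
  stopifnot(model$mode == "continued_svd")
  regnet_reconstruct(model, y)
}

#' Regularized null-space network reconstruction
#'
#' Truncated SVD plus a learned component in the numerical kernel of `A`
#' only; the addition is annihilated by the forward operator up to
#' `rank_tol`.
#'
#' @param model A [regnet_model()] with `mode = "null_space"`.
#' @param y Data vector.
#' @return Domain vector.
#' @export
nullspace_svd_reconstruct <- function(model, y) {
  stopifnot(model$mode == "null_space")
  regnet_reconstruct(model, y)
}

#' Check adaptedness of a model family
#'
#' A family of corrections `N_theta(alpha)` is adapted to a limiting
#' null-space network `N = P_ker(A) U` when
#' `N_theta(alpha)(B_alpha A z) -> N(z)` as `alpha -> 0` for every
#' `z` in the orthogonal complement of the kernel, with uniformly bounded
#' Lipschitz constants. This diagnostic evaluates the defect
#' `e(alpha) = |N_theta(alpha)(B_alpha A z) - N(z)|` for each probe over the
#' model family's decreasing alpha grid, estimates each correction's
#' Lipschitz constant empirically, and flags the family adapted when the
#' defects decrease to below `tol` and the Lipschitz estimates vary by less
#' than a factor 10 (a finite shared bound).
#'
#' @param models List of [regnet_model()]s sharing a system, ordered by
#'   strictly decreasing `alpha` (at least 3).
#' @param reference_network A `network_function` `U`; the limit map is
#'   `N = P_ker(A) U`.
#' @param probes List (or `d x k` matrix) of domain vectors in
#'   `ker(A)^perp`; probes with a kernel component are rejected.
#' @param tol Defect tolerance for the adapted flag (default `1e-6`).
#' @param lip_pairs Probe pairs per Lipschitz estimate (default 50).
#' @param seed Seed for the Lipschitz probes.
#' @return List with `alphas`, `defects` (probe x alpha matrix),
#'   `lipschitz`, and flags `adapted`, `defect_converged`,
#'   `lipschitz_bounded`.
#' @export
check_adaptedness <- function(models, reference_network, probes, tol = 1e-6,
                              lip_pairs = 50L, seed = 1L) {
  stopifnot(length(models) >= 3L)
  alphas <- vapply(models, function(mdl) mdl$alpha, 0)
  stopifnot(all(diff(alphas) < 0))
  sys <- models[[1L]]$system
  if (is.matrix(probes)) probes <- lapply(seq_len(ncol(probes)), function(j) probes[, j])
  for (z in probes) {
    kp <- kernel_projector(sys, z)
    if (l2norm(kp) > 1e-8 * max(l2norm(z), 1)) {
      stop("probe has a kernel component; adaptedness is defined on ker(A)^perp",
           call. = FALSE)
    }
  }
  ref <- vapply(probes, function(z) nullspace_network_apply(sys, reference_network, z),
                numeric(sys$d))
  defects <- matrix(0, length(probes), length(models))
  for (j in seq_along(models)) {
    mdl <- models[[j]]
    for (i in seq_along(probes)) {
      bz <- apply_regularizer(sys, mdl$filter, mdl$alpha,
                              apply_forward(sys, probes[[i]]))
      defects[i, j] <- l2norm(regnet_correction(mdl, bz) - ref[, i])
    }
  }
  lip <- vapply(models, function(mdl) {
    lipschitz_estimate(function(x) regnet_correction(mdl, x), sys$d,
                       n_pairs = lip_pairs, seed = seed)
  }, 0)
  mean_defect <- colMeans(defects)
  defect_converged <- mean_defect[length(models)] <= tol &&
    mean_defect[length(models)] <= mean_defect[1L] + tol
  lip_bounded <- max(lip) <= 10 * max(min(lip), 1e-12) || max(lip) < 1e-8
  list(alphas = alphas, defects = defects, lipschitz = lip,
       defect_converged = defect_converged, lipschitz_bounded = lip_bounded,
       adapted = defect_converged && lip_bounded)
}
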