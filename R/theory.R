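# Numerical embodiment of the convergence analysis: the source-set distance
# function solved exactly in the spectral basis, the error-bound
# decomposition, and empirical convergence-rate measurement.

#' Distance to the shifted source set
#'
#' Computes `d_alpha(x; rho_src, mu) = inf { |x - N_theta(alpha)(B_alpha A x)
#' - (A*A)^mu omega| : |omega| <= rho_src }` exactly in the spectral basis.
#' With the residual `x - N_theta(alpha)(B_alpha A x)` (call it r) and coefficients
#' `r_n = <u_n, r>`, the unconstrained minimizer per positive singular
#' direction is `omega_n = r_n / sigma_n^(2 mu)`. If its norm is within the
#' source radius, the distance is the norm of the component of `r`
#' orthogonal to the range of `(A*A)^mu` (the kernel directions, which no
#' `omega` can match). Otherwise the norm constraint is active and the
#' shifted solution `omega_n(nu) = sigma_n^(2 mu) r_n / (sigma_n^(4 mu) + nu)`
#' is found by solving the monotone secular equation
#' `|omega(nu)| = rho_src` with safeguarded bracketed root-finding to
#' relative `1e-12`.
#'
#' @param system A `spectral_system`.
#' @param model A [regnet_model()] on the same system (use `mode = "plain"`
#'   for the classical, network-free distance).
#' @param x Domain vector.
#' @param rho_src Source radius (positive; the source-condition bound on
#'   `|omega|`).
#' @param mu Positive smoothness order.
#' @return An object of class `distance_result`: `value`, `omega_star`,
#'   `constraint_active`, `nu` (active multiplier or 0), and the residual
#'   vector `residual`.
#' @export
distance_function <- function(system, model, x, rho_src, mu) {
  stopifnot(rho_src > 0, mu > 0, length(x) == system$d)
  b <- apply_regularizer(system, model$filter, model$alpha,
                         apply_forward(system, x))
  r <- x - regnet_correction(model, b)
  sv <- system$singular_values
  pos <- positive_mask(system)
  V <- system$domain_basis
  rc <- drop(crossprod(V, r))
  rp <- rc[pos]
  sp <- sv[pos]
  # kernel directions (stored zero-sigma columns and the unstored
  # complement) cannot be matched by any omega; form the perpendicular
  # component explicitly to avoid cancellation in a difference of norms
  r_perp <- r - as.vector(V[, pos, drop = FALSE] %*% rp)
  perp_sq <- sum(r_perp^2)

  s2m <- sp^(2 * mu)
  w_free <- rp / s2m
  free_norm <- sqrt(sum(w_free^2))
  if (is.finite(free_norm) && free_norm <= rho_src) {
    omega <- as.vector(V[, pos, drop = FALSE] %*% w_free)
    return(structure(list(value = sqrt(perp_sq), omega_star = omega,
                          constraint_active = FALSE, nu = 0, residual = r),
                     class = "distance_result"))
  }
  # secular equation: |omega(nu)| strictly decreasing in nu > 0
  wnorm <- function(nu) sqrt(sum((s2m * rp / (s2m^2 + nu))^2))
  nu_hi <- sqrt(sum((s2m * rp)^2)) / rho_src   # guarantees wnorm(nu_hi) <= rho
  nu_lo <- nu_hi * 1e-30
  while (wnorm(nu_lo) < rho_src && nu_lo > nu_hi * 1e-290) nu_lo <- nu_lo * 1e-10
  root <- uniroot(function(t) wnorm(exp(t)) - rho_src,
                  lower = log(nu_lo), upper = log(nu_hi * (1 + 1e-12)),
                  tol = .Machine$double.eps^0.9, maxiter = 2000L)
  nu <- exp(root$root)
  w <- s2m * rp / (s2m^2 + nu)
  omega <- as.vector(V[, pos, drop = FALSE] %*% w)
  value <- sqrt(perp_sq + sum((rp - s2m * w)^2))
  structure(list(value = value, omega_star = omega, constraint_active = TRUE,
                 nu = nu, residual = r),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> d = %.6g (constraint %s, |omega*| = %.6g)\n",
              x$value, if (x$constraint_active) "active" else "inactive",
              l2norm(x$omega_star)))
  invisible(x)
}

#' Error-bound decomposition of a RegNet reconstruction
#'
#' Evaluates every term of the a-priori error bound
#' `|R_alpha(y_delta) - x| <= delta (1 + L) |B_alpha| + C rho alpha^mu
#' + d_alpha(x; rho, mu) + |B_alpha A N_theta(alpha) B_alpha A x|`
#' together with the realized error, for data `y_delta` with
#' `|A x - y_delta| <= delta`. For the continued SVD, the mixing term
#' vanishes identically (the added band is annihilated by `B_alpha A`).
#'
#' @param system A `spectral_system`.
#' @param model A [regnet_model()].
#' @param x True domain vector.
#' @param y_delta Noisy data vector with `|A x - y_delta| <= delta`.
#' @param delta Noise bound.
#' @param rho_src,mu Source-set parameters.
#' @param C Qualification constant of the filter (see
#'   [qualification_constant()]).
#' @param L Lipschitz bound of the correction family; defaults to the
#'   network's stored empirical estimate (0 for `"plain"`).
#' @return List with `noise_term`, `approximation_term`, `distance_term`,
#'   `mixing_term`, `total_bound`, `true_error` and `bound_holds`.
#' @export
error_bound_terms <- function(system, model, x, y_delta, delta, rho_src, mu,
                              C = 1, L = NULL) {
  misfit <- l2norm(apply_forward(system, x) - y_delta)
  if (misfit > delta * (1 + 1e-10) + 1e-14) {
    stop(sprintf("data misfit %.3g exceeds the stated noise bound delta = %.3g",
                 misfit, delta), call. = FALSE)
  }
  if (is.null(L)) {
    L <- if (model$mode == "plain" || is.null(model$network)) 0 else
      if (!is.null(model$network$lipschitz_estimate)) model$network$lipschitz_estimate else
        lipschitz_estimate(function(z) regnet_correction(model, z), system$d,
                           n_pairs = 50L, seed = 1L)
  }
  noise_term <- delta * (1 + L) * regularizer_norm(system, model$filter, model$alpha)
  approx_term <- C * rho_src * model$alpha^mu
  dist_term <- distance_function(system, model, x, rho_src, mu)$value
  bax <- apply_regularizer(system, model$filter, model$alpha, apply_forward(system, x))
  corr <- regnet_correction(model, bax)
  mixing_term <- l2norm(apply_regularizer(system, model$filter, model$alpha,
                                          apply_forward(system, corr)))
  total <- noise_term + approx_term + dist_term + mixing_term
  true_error <- l2norm(regnet_reconstruct(model, y_delta) - x)
  list(noise_term = noise_term, approximation_term = approx_term,
       distance_term = dist_term, mixing_term = mixing_term,
       total_bound = total, true_error = true_error,
       bound_holds = true_error <= total * (1 + 1e-10))
}

#' Empirical convergence rate over a noise-level grid
#'
#' For each noise level `delta` in a decreasing grid, draws `replicates`
#' noisy data vectors `y_delta = A x + delta * xi` with `xi` uniform on the
#' unit sphere (so the noise bound holds with equality), applies the
#' parameter choice `alpha = c_alpha * delta^(2 / (2 mu + 1))`, reconstructs
#' with the model family, and records the median error. The rate is the
#' ordinary-least-squares slope of `log(error)` versus `log(delta)`;
#' under a source condition of order `mu` and qualification `>= mu` the
#' expected slope is `2 mu / (2 mu + 1)`.
#'
#' @param system A `spectral_system`.
#' @param model_family Function `alpha -> regnet_model`.
#' @param x True solution (typically `(Id + N)(A*A)^mu omega`).
#' @param mu Source smoothness order.
#' @param delta_grid Decreasing noise levels, at least 4 values.
#' @param replicates Noise replicates per level (default 11).
#' @param seed Master noise seed.
#' @param c_alpha Proportionality constant of the parameter choice
#'   (default 1; the slope is insensitive to it).
#' @return An object of class `rate_report`: `delta_grid`, `alphas`,
#'   `errors` (median per level), `slope`, `expected_slope`, `replicates`,
#'   `seed`.
#' @export
empirical_rate <- function(system, model_family, x, mu, delta_grid,
                           replicates = 11L, seed = 1L, c_alpha = 1) {
  if (length(delta_grid) < 4L) {
    stop("`delta_grid` must contain at least 4 noise levels", call. = FALSE)
  }
  stopifnot(all(diff(delta_grid) < 0), all(delta_grid > 0), mu > 0)
  y_clean <- apply_forward(system, x)
  m <- system$m
  errors <- numeric(length(delta_grid))
  alphas <- c_alpha * delta_grid^(2 / (2 * mu + 1))
  for (i in seq_along(delta_grid)) {
    mdl <- model_family(alphas[i])
    errs <- vapply(seq_len(replicates), function(rep) {
      xi <- with_seed(derive_seed(seed, 6L, i * 1000L + rep), rnorm(m))
      xi <- xi / l2norm(xi)
      l2norm(regnet_reconstruct(mdl, y_clean + delta_grid[i] * xi) - x)
    }, 0)
    errors[i] <- median(errs)
  }
  fit <- lm(log(errors) ~ log(delta_grid))
  structure(list(delta_grid = delta_grid, alphas = alphas, errors = errors,
                 slope = unname(coef(fit)[2L]),
                 expected_slope = 2 * mu / (2 * mu + 1),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 c_alpha = c_alpha),
            class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("<rate_report> fitted slope %.4f (expected %.4f) over %d noise levels, %d replicates\n",
              x$slope, x$expected_slope, length(x$delta_grid), x$replicates))
  invisible(x)
}
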