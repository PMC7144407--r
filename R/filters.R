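# Regularizing filters g_alpha(lambda) and empirical qualification estimation.

#' Tikhonov and truncated-SVD filter functions
#'
#' `tikhonov_filter(lambda, alpha) = 1 / (lambda + alpha)`.
#' `tsvd_filter(lambda, alpha)` is `0` for `lambda < alpha` and `1 / lambda`
#' for `lambda >= alpha` (inclusive cutoff).
#'
#' @param lambda Spectrum value(s) in `[0, |A*A|]`, vectorized.
#' @param alpha Positive regularization parameter (scalar).
#' @return Filter value(s).
#' @export
tikhonov_filter <- function(lambda, alpha) {
  stopifnot(alpha > 0, all(lambda >= 0))
  1 / (lambda + alpha)
}

#' @rdname tikhonov_filter
#' @export
tsvd_filter <- function(lambda, alpha) {
  stopifnot(alpha > 0, all(lambda >= 0))
  ifelse(lambda >= alpha, 1 / pmax(lambda, .Machine$double.xmin), 0)
}

#' Construct a regularizing-filter specification
#'
#' A `filter_spec` couples the scalar filter map `g_alpha(lambda)` with its
#' declared qualification order (the largest `mu_0` such that
#' `sup_lambda lambda^mu |1 - lambda g_alpha(lambda)| <= C alpha^mu` for all
#' `mu <= mu_0`): 1 for Tikhonov, infinite for truncated SVD.
#'
#' @param name `"tikhonov"`, `"tsvd"`, or any identifier for a custom filter.
#' @param g Optional custom filter function `g(lambda, alpha)` (vectorized in
#'   `lambda`); required when `name` is not one of the built-ins.
#' @param qualification Declared qualification order (positive real or `Inf`);
#'   filled in automatically for the built-ins.
#' @param stability_bound Declared bound on `sup |lambda g_alpha(lambda)|`;
#'   1 for both built-ins.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(name, g = NULL, qualification = NULL, stability_bound = NULL) {
  name <- as.character(name)
  if (is.null(g)) {
    g <- switch(name,
      tikhonov = tikhonov_filter,
      tsvd = tsvd_filter,
      stop(sprintf("unknown filter '%s'; supply `g` for custom filters", name),
           call. = FALSE)
    )
    if (is.null(qualification)) {
      qualification <- switch(name, tikhonov = 1, tsvd = Inf)
    }
    if (is.null(stability_bound)) stability_bound <- 1
  }
  structure(list(name = name, g = g,
                 declared_qualification = qualification,
                 stability_bound = stability_bound),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s (qualification %s)\n", x$name,
              format(x$declared_qualification)))
  invisible(x)
}

# Shared lambda grid for spectral suprema: log-spaced plus the origin. The
# maximizer of lambda^mu * alpha / (lambda + alpha) migrates toward 0 with
# alpha, so the grid spans 12 decades below lambda_max.
qualification_lambda_grid <- function(lambda_max, n = 2048L) {
  c(0, exp(seq(log(1e-12 * lambda_max), log(lambda_max), length.out = n)))
}

#' Estimate the qualification order of a regularizing filter
#'
#' For each smoothness order `mu` in `mu_grid` and each `alpha` in
#' `alpha_grid`, computes the normalized residual-decay ratio
#' `r(mu, alpha) = sup_lambda [ lambda^mu |1 - lambda g_alpha(lambda)| ] / alpha^mu`
#' over a dense lambda grid in `[0, lambda_max]`. The qualification is the
#' largest tested `mu` whose ratio sequence stays bounded along decreasing
#' `alpha` while every larger tested `mu` diverges. A filter whose stability
#' factor `sup |lambda g_alpha(lambda)|` itself diverges along the alpha grid
#' is rejected (it is not a regularizing filter).
#'
#' Boundedness is declared when `r(mu, .)` varies by less than a factor 3
#' across the alpha grid; divergence when the log-log slope of `r` versus
#' `alpha` is below `-0.1`.
#'
#' @param filter A [filter_spec()].
#' @param mu_grid Positive smoothness orders to test.
#' @param alpha_grid Decreasing positive regularization parameters; should
#'   span at least five decades.
#' @param lambda_max Upper end of the spectrum (use `sigma_1^2`).
#' @return List with `qualification` (estimated order; capped at
#'   `max(mu_grid)` when every tested order is bounded, with `capped = TRUE`),
#'   `ratios` (length(mu_grid) x length(alpha_grid) matrix), `bounded`,
#'   `slopes` and the per-alpha stability factors.
#' @export
estimate_qualification <- function(filter, mu_grid, alpha_grid,
                                   lambda_max = 1) {
  stopifnot(inherits(filter, "filter_spec"),
            length(mu_grid) >= 1L, all(mu_grid > 0),
            length(alpha_grid) >= 2L, all(alpha_grid > 0),
            all(diff(alpha_grid) < 0))
  span <- log10(alpha_grid[1L] / alpha_grid[length(alpha_grid)])
  if (span < 5) stop("`alpha_grid` must span at least 5 decades", call. = FALSE)
  mu_grid <- sort(mu_grid)
  lam <- qualification_lambda_grid(lambda_max)

  stability <- vapply(alpha_grid, function(a) max(abs(lam * filter$g(lam, a))), 0)
  if (any(!is.finite(stability))) {
    stop("filter has non-finite stability factor sup |lambda g_alpha(lambda)|",
         call. = FALSE)
  }
  stab_slope <- unname(coef(lm(log(pmax(stability, 1e-300)) ~ log(alpha_grid)))[2L])
  if (max(stability) / max(min(stability), 1e-300) > 3 && stab_slope < -0.1) {
    stop("filter violates uniform boundedness of lambda * g_alpha(lambda): not a regularizing filter",
         call. = FALSE)
  }

  ratios <- matrix(NA_real_, length(mu_grid), length(alpha_grid),
                   dimnames = list(paste0("mu=", mu_grid), paste0("alpha=", alpha_grid)))
  for (j in seq_along(alpha_grid)) {
    resid <- abs(1 - lam * filter$g(lam, alpha_grid[j]))
    # double-precision floor: a residual at rounding-noise level (e.g.
    # lambda * (1/lambda) differing from 1 by one ulp above the TSVD cutoff)
    # is exact annihilation; without the floor it would be amplified by
    # alpha^-mu
    resid[resid < 1e-13] <- 0
    for (i in seq_along(mu_grid)) {
      ratios[i, j] <- max(lam^mu_grid[i] * resid) / alpha_grid[j]^mu_grid[i]
    }
  }

  la <- log(alpha_grid)
  slopes <- apply(ratios, 1L, function(r) {
    unname(coef(lm(log(pmax(r, 1e-300)) ~ la))[2L])
  })
  variation <- apply(ratios, 1L, function(r) max(r) / max(min(r), 1e-300))
  bounded <- variation < 3
  divergent <- slopes < -0.1

  capped <- all(bounded)
  qualification <- if (capped) {
    max(mu_grid)
  } else {
    ok <- vapply(seq_along(mu_grid), function(i) {
      bounded[i] && all(divergent[mu_grid > mu_grid[i]])
    }, TRUE)
    if (!any(ok)) stop("no tested mu qualifies as bounded with all larger orders divergent",
                       call. = FALSE)
    max(mu_grid[ok])
  }

  list(qualification = qualification, capped = capped, ratios = ratios,
       bounded = bounded, slopes = slopes, stability = stability,
       mu_grid = mu_grid, alpha_grid = alpha_grid)
}

#' Empirical qualification constant
#'
#' The constant `C` realizing
#' `sup_lambda lambda^mu |1 - lambda g_alpha(lambda)| <= C alpha^mu` on the
#' tested grids: the maximum ratio over all `mu <= mu0` and all alphas.
#'
#' @param qual Result of [estimate_qualification()].
#' @param mu0 Orders up to which the bound is certified (default: the
#'   estimated qualification).
#' @return Scalar `C`.
#' @export
qualification_constant <- function(qual, mu0 = qual$qualification) {
  keep <- qual$mu_grid <= mu0
  max(qual$ratios[keep, , drop = FALSE])
}
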