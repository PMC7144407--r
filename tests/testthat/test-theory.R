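test_that("distance function vanishes exactly on the source set", {
  sys <- random_system(5, 8, seed = 81)
  plain <- regnet_model(sys, tsvd, 0.05, mode = "plain")
  res0 <- distance_function(sys, plain, numeric(8), rho_src = 1, mu = 0.5)
  expect_equal(res0$value, 0)
  expect_equal(res0$omega_star, numeric(8))

  omega0 <- regnet:::with_seed(82, rnorm(8))
  omega0 <- omega0 / sqrt(sum(omega0^2)) * 0.9        # inside the ball
  x <- source_element(sys, 0.7, omega0)
  res <- distance_function(sys, plain, x, rho_src = 1, mu = 0.7)
  expect_lt(res$value, 1e-10)
  expect_false(res$constraint_active)
})

test_that("distance function matches two independent brute-force solvers", {
  for (seed in 1:20) {
    d <- 4L + (seed %% 5L)
    sys <- random_system(d + 1L, d, seed = 900 + seed)
    mu <- c(0.5, 1, 1.5)[1L + seed %% 3L]
    rho <- c(0.05, 0.5, 5)[1L + seed %% 3L]
    plain <- regnet_model(sys, tsvd, 0.02, mode = "plain")
    x <- regnet:::with_seed(950 + seed, rnorm(d))
    res <- distance_function(sys, plain, x, rho_src = rho, mu = mu)
    expect_close(sqrt(sum((res$residual - source_element(sys, mu, res$omega_star))^2)),
                 res$value, 1e-10)
    expect_lte(sqrt(sum(res$omega_star^2)), rho * (1 + 1e-10))
    M <- power_matrix(sys, mu)
    scale <- sqrt(sum(res$residual^2))   # reference scale when the optimum is ~0
    v1 <- brute_force_multiplier(M, res$residual, rho)
    expect_lt(abs(res$value - v1), 1e-6 * max(v1, scale))
    # the first-order oracle only converges within budget for mu <= 1 (the
    # mu = 1.5 quadratic has condition number ~ cond(A)^12); the multiplier
    # sweep above covers every case
    if (seed <= 6 && mu <= 1) {
      v2 <- projected_gradient(M, res$residual, rho)
      expect_lt(abs(res$value - v2), 1e-4 * max(v2, scale))
    }
  }
})

test_that("distance is non-increasing in the source radius", {
  sys <- random_system(6, 6, seed = 83)
  plain <- regnet_model(sys, tikh, 0.1, mode = "plain")
  x <- regnet:::with_seed(84, rnorm(6))
  rhos <- c(0.01, 0.1, 1, 10)
  vals <- vapply(rhos, function(r)
    distance_function(sys, plain, x, rho_src = r, mu = 1)$value, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("constant null-space networks give distance decay of order alpha^mu", {
  sys <- random_system(6, 10, seed = 85)
  sys <- svd_decompose(as.matrix(sys$matrix) / sys$singular_values[1L])
  U <- network_function(function(x) 0.5 * tanh(x), "limit map")
  mu <- 1; rho <- 2
  omega0 <- regnet:::with_seed(86, rnorm(10))
  omega0 <- omega0 / sqrt(sum(omega0^2)) * rho * 0.5
  z <- source_element(sys, mu, omega0)
  x <- z + nullspace_network_apply(sys, U, z)      # (Id + N) (A*A)^mu omega
  alphas <- 10^seq(-2, -6, by = -1)
  L <- lipschitz_estimate(function(v) nullspace_network_apply(sys, U, v),
                          dim = 10, n_pairs = 100L, seed = 87)
  vals <- vapply(alphas, function(a) {
    mdl <- regnet_model(sys, tsvd, a, network = U, mode = "null_space")
    distance_function(sys, mdl, x, rho_src = rho, mu = mu)$value
  }, 0)
  # d_alpha <= L * C * alpha^mu with C = 1 for truncated SVD
  expect_true(all(vals <= pmax(L, 1) * alphas^mu + 1e-12))
})

test_that("every term of the error bound dominates the realized error", {
  q <- estimate_qualification(tikh, c(0.5, 1), 10^seq(-1, -8, by = -0.5), 1)
  C <- qualification_constant(q)
  ok <- 0L
  for (seed in 1:50) {
    d <- 5L + seed %% 4L
    sys <- random_system(d, d + 2L, seed = 700 + seed)
    sys <- svd_decompose(as.matrix(sys$matrix) / sys$singular_values[1L])
    mu <- c(0.5, 1)[1L + seed %% 2L]
    rho <- 1.5
    omega0 <- regnet:::with_seed(750 + seed, rnorm(d + 2L))
    omega0 <- omega0 / sqrt(sum(omega0^2)) * rho * 0.8
    x <- source_element(sys, mu, omega0)
    alpha <- c(1e-1, 1e-2, 1e-3)[1L + seed %% 3L]
    delta <- c(1e-2, 1e-3)[1L + seed %% 2L]
    xi <- regnet:::with_seed(760 + seed, rnorm(sys$m))
    y_delta <- apply_forward(sys, x) + delta * xi / sqrt(sum(xi^2))
    mdl <- regnet_model(sys, tikh, alpha, mode = "plain")
    terms <- error_bound_terms(sys, mdl, x, y_delta, delta, rho, mu, C = C)
    expect_true(terms$bound_holds)
    ok <- ok + terms$bound_holds
  }
  expect_equal(ok, 50L)
})

test_that("noise-free bound reduces to the approximation term for source elements", {
  sys <- random_system(6, 6, seed = 88)
  sys <- svd_decompose(as.matrix(sys$matrix) / sys$singular_values[1L])
  rho <- 1; mu <- 1
  omega0 <- regnet:::with_seed(89, rnorm(6))
  omega0 <- omega0 / sqrt(sum(omega0^2)) * rho * 0.7
  x <- source_element(sys, mu, omega0)
  mdl <- regnet_model(sys, tikh, 1e-2, mode = "plain")
  terms <- error_bound_terms(sys, mdl, x, apply_forward(sys, x), 0, rho, mu, C = 1)
  expect_equal(terms$noise_term, 0)
  expect_lt(terms$distance_term, 1e-10)
  expect_equal(terms$mixing_term, 0)
  expect_equal(terms$total_bound, terms$approximation_term +
                 terms$distance_term + terms$mixing_term)
})

test_that("the mixing term vanishes identically for the continued SVD", {
  sys <- random_system(6, 9, seed = 90)
  alpha <- stats::median(sys$singular_values)^2
  net <- network_function(function(x) x + 1, "offset probe")
  mdl <- regnet_model(sys, tsvd, alpha, network = net, mode = "continued_svd")
  x <- regnet:::with_seed(91, rnorm(9))
  terms <- error_bound_terms(sys, mdl, x, apply_forward(sys, x), 0,
                             rho_src = 1, mu = 1, C = 1, L = 2)
  expect_lt(terms$mixing_term, 1e-12)
})

test_that("rate measurement rejects short grids and misfit data", {
  sys <- diagonal_system((1:20)^-1)
  fam <- function(a) regnet_model(sys, tikh, a, mode = "plain")
  expect_error(empirical_rate(sys, fam, rnorm(20), 1, c(1e-1, 1e-2, 1e-3)),
               "at least 4")
  mdl <- fam(0.1)
  x <- regnet:::with_seed(92, rnorm(20))
  expect_error(error_bound_terms(sys, mdl, x, apply_forward(sys, x) + 1,
                                 delta = 1e-6, rho_src = 1, mu = 1),
               "noise bound")
})

test_that("errors decrease monotonically when only the parameter rule varies", {
  # zero injected noise: the reconstruction error is pure approximation
  # error, which shrinks with alpha = delta^(2/(2 mu + 1))
  sys <- diagonal_system((1:50)^-1)
  omega <- regnet:::with_seed(93, rnorm(50))
  x <- source_element(sys, 1, omega)
  errs <- vapply(10^seq(-1, -4, by = -1), function(delta) {
    a <- delta^(2 / 3)
    sqrt(sum((apply_regularizer(sys, tikh, a, apply_forward(sys, x)) - x)^2))
  }, 0)
  expect_true(all(diff(errs) < 0))
})
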