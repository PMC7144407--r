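test_that("svd_decompose recovers closed-form singular systems", {
  sys <- svd_decompose(diag(3))
  expect_close(sys$singular_values, c(1, 1, 1))

  sys <- svd_decompose(diag(c(2, 1, 0)))
  expect_close(sys$singular_values, c(2, 1, 0))
  # third domain vector spans the kernel
  expect_close(abs(sys$domain_basis[3L, 3L]), 1)
  expect_close(diag(c(2, 1, 0)) %*% sys$domain_basis[, 3L], numeric(3))
})

test_that("svd_decompose factors reproduce the matrix and stay orthonormal", {
  A <- regnet:::with_seed(11, matrix(rnorm(60), 6, 10))
  sys <- svd_decompose(A)
  # independent oracle: eigenvalues of A A' give the squared singular values
  ref_d <- sqrt(pmax(0, eigen(tcrossprod(A), symmetric = TRUE)$values))
  expect_close(sys$singular_values, ref_d, 1e-9)
  recon <- sys$range_basis %*% (sys$singular_values * t(sys$domain_basis))
  expect_lt(max(abs(recon - A)), 1e-8 * sys$singular_values[1L])
  expect_close(crossprod(sys$domain_basis), diag(6), 1e-10)
  expect_close(crossprod(sys$range_basis), diag(6), 1e-10)
  # A u_n = sigma_n v_n and A' v_n = sigma_n u_n
  expect_lt(max(abs(A %*% sys$domain_basis -
                    sys$range_basis %*% diag(sys$singular_values))),
            1e-10 * sys$singular_values[1L])
  expect_lt(max(abs(t(A) %*% sys$range_basis -
                    sys$domain_basis %*% diag(sys$singular_values))),
            1e-10 * sys$singular_values[1L])
})

test_that("svd_decompose rejects non-finite matrices and bad tolerances", {
  expect_error(svd_decompose(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
  expect_error(svd_decompose(diag(2), rank_tol = 2), "rank_tol")
})

test_that("apply_spectral_function matches closed forms and dense solves", {
  sys <- svd_decompose(diag(c(2, 1)))
  expect_close(apply_spectral_function(sys, function(l) l * 0 + 1, c(0.3, -2)),
               c(0.3, -2))
  expect_close(apply_spectral_function(sys, identity, c(1, 1)), c(4, 1))

  sys5 <- random_system(5, 5, seed = 2)
  A <- as.matrix(sys5$matrix)
  x <- regnet:::with_seed(3, rnorm(5))
  got <- apply_spectral_function(sys5, function(l) 1 / (l + 1), x)
  want <- solve(crossprod(A) + diag(5), x)
  expect_close(got, want, 1e-10)
})

test_that("apply_spectral_function is linear and errors on non-finite values", {
  sys <- random_system(4, 6, seed = 5)
  f <- function(l) sqrt(l + 0.1)
  x <- regnet:::with_seed(6, rnorm(6)); z <- regnet:::with_seed(7, rnorm(6))
  expect_close(apply_spectral_function(sys, f, 2 * x - 3 * z),
               2 * apply_spectral_function(sys, f, x) -
               3 * apply_spectral_function(sys, f, z), 1e-12)
  expect_error(apply_spectral_function(sys, function(l) 1 / l, x), "non-finite")
})

test_that("filter functions evaluate the printed formulas", {
  expect_equal(tikhonov_filter(1, 1), 0.5)
  expect_equal(tikhonov_filter(0, 0.25), 4)
  # fixed lambda, shrinking alpha: monotone approach to 1/lambda
  vals <- vapply(10^-(1:6), function(a) tikhonov_filter(0.3, a), 0)
  expect_true(all(diff(vals) > 0))
  expect_lt(abs(vals[6L] - 1 / 0.3), 1e-4)

  expect_equal(tsvd_filter(0.5, 1), 0)
  expect_equal(tsvd_filter(2, 1), 0.5)
  expect_equal(tsvd_filter(1, 1), 1)   # inclusive cutoff
  # sup over lambda of lambda * g_alpha(lambda) is exactly 1 for every alpha
  lam <- seq(0, 10, by = 0.01)
  for (a in c(0.1, 1, 3)) expect_equal(max(lam * tsvd_filter(lam, a)), 1)
})

test_that("apply_regularizer matches dense solve and pseudoinverse oracles", {
  sys <- random_system(8, 8, seed = 8)
  A <- as.matrix(sys$matrix)
  y <- regnet:::with_seed(9, rnorm(8))
  expect_close(apply_regularizer(sys, tikh, 0.3, y * 0), numeric(8))
  got <- apply_regularizer(sys, tikh, 0.3, y)
  want <- solve(crossprod(A) + 0.3 * diag(8), crossprod(A, y))
  expect_close(got, want, 1e-10)

  # TSVD below the smallest positive sigma^2, y in ran(A): minimum-norm solution
  sys2 <- random_system(6, 9, seed = 10)
  A2 <- as.matrix(sys2$matrix)
  y2 <- as.vector(A2 %*% regnet:::with_seed(11, rnorm(9)))
  alpha <- 0.5 * min(sys2$singular_values[sys2$singular_values > 0])^2
  got2 <- apply_regularizer(sys2, tsvd, alpha, y2)
  want2 <- MASS::ginv(A2) %*% y2
  expect_close(got2, want2, 1e-9)
})

test_that("regularized reconstructions converge to the pseudoinverse as alpha -> 0", {
  for (seed in 1:3) {
    sys <- random_system(7, 10, seed = seed)
    A <- as.matrix(sys$matrix)
    y <- as.vector(A %*% regnet:::with_seed(seed + 50, rnorm(10)))
    pinv_y <- as.vector(MASS::ginv(A) %*% y)
    for (filt in list(tikh, tsvd)) {
      expect_close(apply_regularizer(sys, filt, 1e-10, y), pinv_y, 1e-6)
    }
  }
})

test_that("source_element obeys power identities", {
  sys <- svd_decompose(diag(c(2, 1)))
  expect_close(source_element(sys, 0, c(0.7, -0.2)), c(0.7, -0.2))
  expect_close(source_element(sys, 0.5, c(1, 1)), c(2, 1))

  sys2 <- random_system(5, 7, seed = 12)
  A <- as.matrix(sys2$matrix)
  w <- regnet:::with_seed(13, rnorm(7))
  expect_close(source_element(sys2, 1, w), as.vector(crossprod(A, A %*% w)), 1e-10)
})

test_that("kernel_projector projects onto the numerical kernel and is idempotent", {
  sys <- random_system(4, 4, seed = 14)         # full rank square
  x <- regnet:::with_seed(15, rnorm(4))
  expect_close(kernel_projector(sys, x), numeric(4), 1e-9)
  expect_close(kernel_projector(sys, sys$domain_basis[, 1L]), numeric(4), 1e-10)

  sysd <- svd_decompose(diag(c(1, 0)))
  expect_close(kernel_projector(sysd, c(3, 5)), c(0, 5))

  sysr <- random_system(5, 9, seed = 16)
  z <- regnet:::with_seed(17, rnorm(9))
  p1 <- kernel_projector(sysr, z)
  expect_close(kernel_projector(sysr, p1), p1, 1e-12)
  expect_lt(sqrt(sum(apply_forward(sysr, p1)^2)),
            1e-9 * sysr$singular_values[1L] * sqrt(sum(z^2)))
})
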