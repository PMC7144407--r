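test_that("null-space network applications land in the kernel", {
  sys <- random_system(4, 4, seed = 41)   # full rank: trivial kernel
  some_net <- network_function(function(x) x + 1, "affine probe")
  x <- regnet:::with_seed(42, rnorm(4))
  expect_close(nullspace_network_apply(sys, zero_network(), x), numeric(4))
  expect_close(nullspace_network_apply(sys, some_net, x), numeric(4), 1e-9)

  sysd <- svd_decompose(diag(c(1, 0)))
  out <- nullspace_network_apply(sysd, some_net, c(3, 5))
  expect_equal(out[1L], 0)
})

test_that("plain mode reproduces the filter regularizer exactly", {
  sys <- toy_radon_system()
  mdl <- regnet_model(sys, tsvd, 0.01, mode = "plain")
  y <- regnet:::with_seed(43, rnorm(sys$m))
  expect_identical(regnet_reconstruct(mdl, y),
                   apply_regularizer(sys, tsvd, 0.01, y))
})

test_that("reconstruction equals the unrolled two-step composition", {
  sys <- random_system(6, 10, seed = 44)
  net <- network_function(function(x) tanh(x), "tanh probe")
  mdl <- regnet_model(sys, tsvd, 0.05, network = net, mode = "continued_svd")
  y <- regnet:::with_seed(45, rnorm(6))
  b <- apply_regularizer(sys, tsvd, 0.05, y)
  manual <- b + regnet:::project_band(mdl, matrix(network_apply(net, b), ncol = 1))
  expect_identical(regnet_reconstruct(mdl, y), drop(manual))
  # zero-preserving network on zero data gives zero
  expect_close(regnet_reconstruct(mdl, numeric(6)), numeric(10))
})

test_that("continued SVD preserves retained coefficients and extends the rest", {
  sys <- random_system(8, 12, seed = 46)
  alpha <- stats::median(sys$singular_values)^2
  net <- network_function(function(x) x + 0.3, "offset probe")
  mdl <- regnet_model(sys, tsvd, alpha, network = net, mode = "continued_svd")
  y <- regnet:::with_seed(47, rnorm(8))
  b <- apply_regularizer(sys, tsvd, alpha, y)
  out <- continued_svd_reconstruct(mdl, y)
  retained <- sys$singular_values^2 >= alpha
  U <- sys$domain_basis
  expect_close(crossprod(U[, retained, drop = FALSE], out),
               crossprod(U[, retained, drop = FALSE], b), 1e-12)
  # zero network: exactly the truncated SVD
  mdl0 <- regnet_model(sys, tsvd, alpha, network = zero_network(),
                       mode = "continued_svd")
  expect_close(continued_svd_reconstruct(mdl0, y), b, 1e-12)
})

test_that("continued SVD matches a hand-enumerated spectral sum on diag(2,1,0.1)", {
  sys <- diagonal_system(c(2, 1, 0.1))
  alpha <- 0.5
  idnet <- network_function(identity, "identity")
  mdl <- regnet_model(sys, tsvd, alpha, network = idnet, mode = "continued_svd")
  y <- c(0.7, -1.2, 0.4)
  # hand evaluation: sigma^2 = (4, 1, 0.01); retained sigma^2 >= 0.5 -> first two
  b_hand <- c(y[1] / 2, y[2] / 1, 0)
  u3 <- c(0, 0, 1)
  out_hand <- b_hand + sum(b_hand * u3) * u3    # truncated band gets <U(b), u3> u3
  expect_close(continued_svd_reconstruct(mdl, y), out_hand, 1e-12)
})

test_that("null-space mode only adds components invisible to the operator", {
  sys <- random_system(7, 12, seed = 48)
  alpha <- stats::median(sys$singular_values)^2
  net <- network_function(function(x) sin(x), "sin probe")
  mdl <- regnet_model(sys, tsvd, alpha, network = net, mode = "null_space")
  y <- regnet:::with_seed(49, rnorm(7))
  b <- apply_regularizer(sys, tsvd, alpha, y)
  added <- nullspace_svd_reconstruct(mdl, y) - b
  expect_gt(sqrt(sum(added^2)), 0)
  expect_lt(sqrt(sum(apply_forward(sys, added)^2)),
            1e-8 * sys$singular_values[1L] * sqrt(sum(added^2)))

  # full-rank system: empty kernel band, output equals B_alpha y
  sysf <- random_system(5, 5, seed = 50)
  mdlf <- regnet_model(sysf, tsvd, 1e-8, network = net, mode = "null_space")
  yf <- regnet:::with_seed(51, rnorm(5))
  expect_close(nullspace_svd_reconstruct(mdlf, yf),
               apply_regularizer(sysf, tsvd, 1e-8, yf), 1e-9)
})

test_that("learned modes require the truncated-SVD filter", {
  sys <- random_system(4, 6, seed = 52)
  expect_error(regnet_model(sys, tikh, 0.1, network = zero_network(),
                            mode = "continued_svd"), "truncated-SVD")
  expect_error(regnet_model(sys, tikh, 0.1, network = zero_network(),
                            mode = "null_space"), "truncated-SVD")
})

test_that("the continued-SVD band is annihilated by B_alpha A", {
  # condition (A3): B_alpha A N_theta(alpha) B_alpha A x = 0 exactly
  for (seed in 1:5) {
    sys <- random_system(6, 9, seed = seed)
    alpha <- stats::median(sys$singular_values)^2
    net <- network_function(function(x) x^2 + 1, "nonlinear probe")
    mdl <- regnet_model(sys, tsvd, alpha, network = net, mode = "continued_svd")
    x <- regnet:::with_seed(seed + 60, rnorm(9))
    bax <- apply_regularizer(sys, tsvd, alpha, apply_forward(sys, x))
    corr <- regnet:::regnet_correction(mdl, bax)
    mixing <- apply_regularizer(sys, tsvd, alpha, apply_forward(sys, corr))
    expect_close(mixing, numeric(9), 1e-12)
  }
})

test_that("adaptedness diagnostics accept constant families and reject scaled ones", {
  sys <- random_system(6, 9, seed = 70)
  alphas <- 10^c(-2, -4, -6, -8)
  below <- min(sys$singular_values[sys$singular_values > 1e-10]^2)
  alphas <- alphas * below            # push the whole grid under sigma_min^2
  U <- network_function(function(x) tanh(x) + 0.1, "limit map")

  # zero networks with zero reference: zero defect everywhere
  zero_models <- lapply(alphas, function(a)
    regnet_model(sys, tsvd, a, network = zero_network(), mode = "null_space"))
  rep0 <- check_adaptedness(zero_models, zero_network(),
                            probes = list(sys$domain_basis[, 1L]))
  expect_true(all(rep0$defects == 0))
  expect_true(rep0$adapted)

  # constant null-space family: adapted (B_alpha A z -> z on ker(A)^perp)
  const_models <- lapply(alphas, function(a)
    regnet_model(sys, tsvd, a, network = U, mode = "null_space"))
  z <- sys$domain_basis[, 2L]
  repc <- check_adaptedness(const_models, U, probes = list(z))
  expect_true(repc$adapted)
  expect_true(all(diff(colMeans(repc$defects)) <= 1e-12))

  # output scaled by 1/alpha: Lipschitz bound diverges -> not adapted
  scaled_models <- lapply(alphas, function(a) {
    regnet_model(sys, tsvd, a,
                 network = network_function(function(x) x / a, "1/alpha blowup"),
                 mode = "null_space")
  })
  reps <- check_adaptedness(scaled_models, U, probes = list(z))
  expect_false(reps$lipschitz_bounded)
  expect_false(reps$adapted)

  # probes with kernel components are rejected
  kvec <- kernel_projector(sys, regnet:::with_seed(71, rnorm(9)))
  expect_error(check_adaptedness(const_models, U, probes = list(kvec)),
               "kernel component")
})
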