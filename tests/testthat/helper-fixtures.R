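# Shared fixtures: small random systems and geometries, built in code.

random_system <- function(m, d, seed, rank_tol = 1e-10) {
  A <- regnet:::with_seed(seed, matrix(rnorm(m * d), m, d))
  svd_decompose(A, rank_tol = rank_tol)
}

# tiny Radon geometry for end-to-end plumbing tests
toy_geometry <- function(grid_n = 16L, n_angles = 6L, n_offsets = 24L) {
  projection_geometry(grid_n = grid_n, n_angles = n_angles, n_offsets = n_offsets)
}

toy_radon_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- svd_decompose(build_operator(toy_geometry()))
    cache
  }
})

tsvd <- filter_spec("tsvd")
tikh <- filter_spec("tikhonov")

expect_close <- function(object, expected, tol = 1e-10) {
  expect_lt(max(abs(object - expected)), tol)
}
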