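# Independent brute-force solvers for the constrained source-set projection
# min |r - M omega| over |omega| <= rho, used to cross-check the spectral
# secular-equation solver.

# (1) dense ridge sweep over the constraint multiplier with log-bisection
brute_force_multiplier <- function(M, r, rho) {
  MtM <- crossprod(M)
  Mtr <- crossprod(M, r)
  omega_of <- function(nu) solve(MtM + nu * diag(nrow(MtM)), Mtr)
  val_of <- function(omega) sqrt(sum((r - M %*% omega)^2))
  o0 <- tryCatch(qr.solve(MtM + 1e-300 * diag(nrow(MtM)), Mtr),
                 error = function(e) NULL)
  if (!is.null(o0) && all(is.finite(o0)) && sqrt(sum(o0^2)) <= rho) return(val_of(o0))
  lo <- 1e-18; hi <- 1e6
  while (sqrt(sum(omega_of(hi)^2)) > rho) hi <- hi * 10
  while (sqrt(sum(omega_of(lo)^2)) < rho && lo > 1e-300) lo <- lo / 10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (sqrt(sum(omega_of(mid)^2)) > rho) lo <- mid else hi <- mid
  }
  val_of(omega_of(sqrt(lo * hi)))
}

# (2) projected gradient descent on the norm ball
projected_gradient <- function(M, r, rho, iters = 20000L) {
  d <- ncol(M)
  omega <- numeric(d)
  step <- 1 / (norm(M, "2")^2 + 1e-12)
  for (i in seq_len(iters)) {
    grad <- -crossprod(M, r - M %*% omega)
    omega <- omega - step * grad
    nrm <- sqrt(sum(omega^2))
    if (nrm > rho) omega <- omega * (rho / nrm)
  }
  sqrt(sum((r - M %*% omega)^2))
}

# dense matrix of (A*A)^mu in the stored spectral basis
power_matrix <- function(sys, mu) {
  V <- sys$domain_basis
  V %*% (sys$singular_values^(2 * mu) * t(V))
}
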