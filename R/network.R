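# Trainable image-to-image networks. The default architecture is a small
# convolutional encoder-decoder with skip connections (3x3 convolutions,
# ReLU, 2x2 mean pooling, nearest-neighbour upsampling), implemented directly
# on BLAS: a 3x3 convolution is nine shifted matrix products. Feature maps
# for a batch of B images of side r are stored as (r*r*B) x channels
# matrices, images stacked block-wise in the canonical pixel order.

# ---- geometry caches (shift permutations, pooling operators) ----

.net_cache <- new.env(parent = emptyenv())

# source-row indices for the nine 3x3 taps at resolution r, batch B: a
# single integer vector of length 9*r*r*B (tap-major), each entry the source
# row for an output row, with r*r*B + 1 the zero-padding sentinel. Taps are
# enumerated so that tap k and tap 10 - k are opposite shifts.
shift_index <- function(r, B) {
  key <- paste0("perm_", r, "_", B)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  npix <- r * r
  n_rows <- npix * B
  sentinel <- n_rows + 1L
  ix <- rep.int(seq_len(r), r)           # first axis, fastest
  jx <- rep(seq_len(r), each = r)
  img_off <- rep(0:(B - 1L) * npix, each = npix)
  perms <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    si <- ix + di
    sj <- jx + dj
    valid <- si >= 1L & si <= r & sj >= 1L & sj <= r
    src <- ifelse(valid, si + (sj - 1L) * r, NA_integer_)
    full <- rep.int(src, B) + ifelse(rep.int(valid, B), img_off, 0L)
    full[is.na(full)] <- sentinel
    perms[[k]] <- as.integer(full)
  }
  idx <- unlist(perms, use.names = FALSE)
  .net_cache[[key]] <- idx
  idx
}

# gather a (n_rows x 9*cin) patch matrix. Weight rows (and hence patch
# columns) are ordered taps-fastest within input channel: column
# (c-1)*9 + k is the tap-k shift of channel c. With that ordering the
# tap-major gather reshapes into the patch matrix by a bare dim<- (no copy).
im2col <- function(X, idx) {
  n_rows <- nrow(X)
  cin <- ncol(X)
  Xa <- rbind(X, 0)
  G <- Xa[idx, , drop = FALSE]                     # (9*n_rows) x cin, tap-major
  dim(G) <- c(n_rows, 9L * cin)
  G
}

# rearrange conv weights (9*cin x cout) into the flipped-kernel form
# (9*cout x cin) used for the input gradient: tap k of the flipped kernel is
# tap 10 - k of the forward kernel, transposed in the channel indices
flip_weights <- function(W, cin, cout) {
  Wa <- array(W, c(9L, cin, cout))
  Wb <- aperm(Wa[9:1, , , drop = FALSE], c(1L, 3L, 2L))
  dim(Wb) <- c(9L * cout, cin)
  Wb
}

# sparse 2x2 mean-pooling operator: (r/2)^2*B x r^2*B, entries 1/4
pool_operator <- function(r, B) {
  key <- paste0("pool_", r, "_", B)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  stopifnot(r %% 2L == 0L)
  rc <- r %/% 2L
  npix_f <- r * r
  npix_c <- rc * rc
  ix <- rep.int(seq_len(r), r)
  jx <- rep(seq_len(r), each = r)
  coarse <- (ix + 1L) %/% 2L + (((jx + 1L) %/% 2L) - 1L) * rc
  rows <- rep.int(coarse, B) + rep(0:(B - 1L) * npix_c, each = npix_f)
  cols <- seq_len(npix_f * B)
  P <- Matrix::sparseMatrix(i = rows, j = cols, x = 0.25,
                            dims = c(npix_c * B, npix_f * B))
  .net_cache[[key]] <- P
  P
}

# ---- convolution primitives ----

# forward: one gather + one GEMM. Hot path in compiled code; the `_ref`
# versions are the plain-R reference implementations the compiled kernels
# are tested against.
conv_fwd <- function(X, W, b, idx) {
  conv_fwd_cpp(X, W, b, idx)
}

conv_fwd_ref <- function(X, W, b, idx) {
  Y <- im2col(X, idx) %*% W
  Y + rep(b, each = nrow(Y))
}

# backward: weight gradient from the re-gathered patches of the cached layer
# input; input gradient as a gather-convolution of dY with the flipped
# kernel (adjoint of the forward shift pattern, so no scatter is needed)
conv_bwd <- function(dY, X, W, idx) {
  conv_bwd_cpp(dY, X, W, idx)
}

conv_bwd_ref <- function(dY, X, W, idx) {
  dW <- crossprod(im2col(X, idx), dY)
  dX <- im2col(dY, idx) %*% flip_weights(W, ncol(X), ncol(W))
  list(dW = dW, db = colSums(dY), dX = dX)
}

# ---- the encoder-decoder ----

#' Convolutional encoder-decoder network
#'
#' Builds a small U-net-style image-to-image network: `scales` resolution
#' levels of two 3x3 convolution + ReLU blocks each, 2x2 mean pooling on the
#' way down, nearest-neighbour upsampling and skip-connection concatenation
#' on the way up, and a final 3x3 convolution to one channel. The final
#' layer is zero-initialized, so a freshly built network is the zero map and
#' trained corrections grow from zero. All weights are seeded; evaluation is
#' deterministic.
#'
#' @param n Image side length; must be divisible by `2^(scales - 1)`.
#' @param base_channels Channels at the finest scale (doubled per level).
#' @param scales Number of resolution levels (`>= 1`).
#' @param seed Seed for the He-style weight initialization.
#' @return An object of classes `conv_net` and `network_function`.
#' @export
conv_net <- function(n, base_channels = 16L, scales = 3L, seed = 1L) {
  stopifnot(scales >= 1L, n %% (2^(scales - 1L)) == 0L, base_channels >= 1L)
  ch <- function(s) as.integer(base_channels * 2^(s - 1L))
  params <- list()
  init <- function(cin, cout, zero = FALSE) {
    W <- if (zero) matrix(0, 9L * cin, cout) else
      matrix(rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))), 9L * cin, cout)
    list(W = W, b = numeric(cout))
  }
  with_seed(seed, {
    for (s in seq_len(scales)) {
      cin <- if (s == 1L) 1L else ch(s - 1L)
      params[[paste0("enc", s, "a")]] <- init(cin, ch(s))
      params[[paste0("enc", s, "b")]] <- init(ch(s), ch(s))
    }
    for (s in rev(seq_len(scales - 1L))) {
      params[[paste0("dec", s, "a")]] <- init(ch(s + 1L) + ch(s), ch(s))
      params[[paste0("dec", s, "b")]] <- init(ch(s), ch(s))
    }
    params[["out"]] <- init(ch(1L), 1L, zero = TRUE)
  })
  structure(list(n = as.integer(n), base_channels = as.integer(base_channels),
                 scales = as.integer(scales), seed = as.integer(seed),
                 params = params,
                 descriptor = sprintf("conv encoder-decoder, %d scales, %d base channels, skip connections",
                                      scales, base_channels),
                 lipschitz_estimate = NULL),
            class = c("conv_net", "network_function"))
}

# forward pass; X is (n*n*B) x 1. Returns y and, optionally, layer caches.
conv_net_forward <- function(net, X, B, keep_cache = FALSE) {
  S <- net$scales
  caches <- list()
  act <- X
  r <- net$n
  skips <- vector("list", S)
  run_conv <- function(name, input, r, relu) {
    idx <- shift_index(r, B)
    p <- net$params[[name]]
    Y <- conv_fwd(input, p$W, p$b, idx)
    out <- if (relu) pmax(Y, 0) else Y
    if (keep_cache) {
      caches[[name]] <<- list(input = input,
                              mask = if (relu) Y > 0 else NULL, r = r)
    }
    out
  }
  for (s in seq_len(S)) {
    if (s > 1L) {
      P <- pool_operator(r, B)
      act <- as.matrix(P %*% act)
      r <- r %/% 2L
    }
    act <- run_conv(paste0("enc", s, "a"), act, r, TRUE)
    act <- run_conv(paste0("enc", s, "b"), act, r, TRUE)
    skips[[s]] <- act
  }
  for (s in rev(seq_len(S - 1L))) {
    P <- pool_operator(r * 2L, B)
    act <- 4 * as.matrix(Matrix::crossprod(P, act))
    r <- r * 2L
    act <- cbind(act, skips[[s]])
    act <- run_conv(paste0("dec", s, "a"), act, r, TRUE)
    act <- run_conv(paste0("dec", s, "b"), act, r, TRUE)
  }
  y <- run_conv("out", act, r, FALSE)
  if (keep_cache) list(y = y, caches = caches) else list(y = y)
}

# backward pass: gradient of a scalar loss wrt all parameters, given dL/dy
conv_net_backward <- function(net, caches, dY, B) {
  S <- net$scales
  grads <- list()
  back_conv <- function(name, dOut) {
    cc <- caches[[name]]
    if (!is.null(cc$mask)) dOut <- dOut * cc$mask
    g <- conv_bwd(dOut, cc$input, net$params[[name]]$W, shift_index(cc$r, B))
    grads[[name]] <<- list(W = g$dW, b = g$db)
    g$dX
  }
  d_act <- back_conv("out", dY)
  d_skip <- vector("list", S)
  for (s in seq_len(S - 1L)) {
    d_act <- back_conv(paste0("dec", s, "b"), d_act)
    d_cat <- back_conv(paste0("dec", s, "a"), d_act)
    ch_up <- ncol(d_cat) - ncol(caches[[paste0("enc", s, "b")]]$mask)
    d_up <- d_cat[, seq_len(ch_up), drop = FALSE]
    d_skip[[s]] <- d_cat[, -seq_len(ch_up), drop = FALSE]
    r <- caches[[paste0("dec", s, "a")]]$r
    P <- pool_operator(r, B)
    d_act <- 4 * as.matrix(P %*% d_up)   # adjoint of nearest upsampling
  }
  for (s in rev(seq_len(S))) {
    if (s < S) d_act <- d_act + d_skip[[s]]
    d_act <- back_conv(paste0("enc", s, "b"), d_act)
    d_act <- back_conv(paste0("enc", s, "a"), d_act)
    if (s > 1L) {
      r <- caches[[paste0("enc", s, "a")]]$r
      P <- pool_operator(r * 2L, B)
      d_act <- as.matrix(Matrix::crossprod(P, d_act))
    }
  }
  grads
}

# ---- generic network-function interface ----

#' Wrap an arbitrary map as a network function
#'
#' Lifts any function acting on coefficient vectors (or images) to the
#' `network_function` interface used by the reconstruction maps. The map is
#' applied column-wise to batches.
#'
#' @param fn Function taking and returning a numeric vector.
#' @param descriptor Human-readable description.
#' @return A `network_function`.
#' @export
network_function <- function(fn, descriptor = "custom map") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, descriptor = descriptor, lipschitz_estimate = NULL),
            class = "network_function")
}

#' The zero network
#' @return A `network_function` mapping everything to zero.
#' @export
zero_network <- function() {
  network_function(function(x) x * 0, "zero map")
}

#' Evaluate a network function on a vector or batch
#'
#' @param network A `network_function` (including [conv_net()]).
#' @param x Numeric vector of length `d`, or a `d x B` matrix of batch
#'   columns.
#' @return Same shape as `x`.
#' @export
network_apply <- function(network, x) {
  UseMethod("network_apply")
}

#' @export
network_apply.conv_net <- function(network, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  stopifnot(nrow(X) == network$n^2)
  B <- ncol(X)
  y <- conv_net_forward(network, matrix(as.vector(X), ncol = 1L), B)$y
  out <- matrix(y, nrow(X), B)
  if (vec) drop(out) else out
}

#' @export
network_apply.network_function <- function(network, x) {
  if (is.null(dim(x))) return(network$fn(x))
  apply(x, 2L, network$fn)
}

#' Empirical Lipschitz estimate of a map
#'
#' Maximum ratio `|F(x1) - F(x2)| / |x1 - x2|` over seeded standard-normal
#' probe pairs; a practical certificate that a family of trained networks
#' shares a finite Lipschitz bound.
#'
#' @param map Function from vectors to vectors (e.g. a reconstruction
#'   correction), or a `network_function`.
#' @param dim Input dimension.
#' @param n_pairs Number of probe pairs (default 200).
#' @param seed Probe seed.
#' @return Non-negative scalar.
#' @export
lipschitz_estimate <- function(map, dim, n_pairs = 200L, seed = 1L) {
  f <- if (inherits(map, "network_function")) function(x) network_apply(map, x) else map
  with_seed(seed, {
    best <- 0
    for (i in seq_len(n_pairs)) {
      x1 <- rnorm(dim)
      x2 <- rnorm(dim)
      best <- max(best, l2norm(f(x1) - f(x2)) / l2norm(x1 - x2))
    }
    best
  })
}
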