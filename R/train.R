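# Training of the per-alpha networks U_theta(alpha): stochastic gradient
# descent with momentum on the mean absolute error of the full
# reconstruction map R_alpha.

#' Training configuration
#'
#' @param learning_rate SGD step size (default 0.05).
#' @param momentum Momentum parameter in `[0, 1)` (default 0.99).
#' @param epochs Number of passes over the dataset (default 100).
#' @param batch_size Minibatch size (default 8).
#' @param seed Seed controlling initialization order and shuffling.
#' @param clip_norm Global gradient-norm clip; `Inf` disables. Default 5:
#'   a numerical safeguard for the aggressive default step size on
#'   summed-per-image absolute losses.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.05, momentum = 0.99,
                            epochs = 100L, batch_size = 8L, seed = 1L,
                            clip_norm = 5) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1L,
            batch_size >= 1L, clip_norm > 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), clip_norm = clip_norm),
            class = "training_config")
}

#' Mean absolute error over a batch
#'
#' Mean over the batch of the entrywise l1 norm of the residual: each
#' sample contributes the sum of absolute coefficient differences, and
#' samples are averaged.
#'
#' @param predictions,targets Matrices with one sample per column (or
#'   vectors for a single sample), identical shapes.
#' @return Non-negative scalar.
#' @export
mae_loss <- function(predictions, targets) {
  P <- as.matrix(predictions)
  Tg <- as.matrix(targets)
  if (!identical(dim(P), dim(Tg))) {
    stop("predictions and targets have different shapes", call. = FALSE)
  }
  mean(colSums(abs(P - Tg)))
}

#' Train a RegNet on a paired dataset
#'
#' Optimizes the network parameters of `U_theta(alpha)` through the full
#' reconstruction map: the loss compares ground-truth coefficients `c^(k)`
#' with `R_alpha(y^(k)) = B_alpha y^(k) + P_band U_theta(B_alpha y^(k))`,
#' where the band projector is fixed by the model's mode and only the
#' network parameters carry gradients. Stochastic gradient descent with
#' momentum on the batch mean absolute error; deterministic per
#' `config$seed`.
#'
#' @param model A [regnet_model()] whose network is a [conv_net()].
#' @param dataset A [make_dataset()] result with `dataset$alpha` equal to
#'   `model$alpha`.
#' @param config A [training_config()].
#' @return List with `model` (trained; the network carries an updated
#'   empirical Lipschitz estimate) and `loss` (per-epoch mean training
#'   loss).
#' @export
train_regnet <- function(model, dataset, config = training_config()) {
  stopifnot(inherits(model, "regnet_model"), inherits(dataset, "regnet_dataset"),
            inherits(config, "training_config"))
  if (model$mode == "plain") stop("mode 'plain' has no trainable parameters", call. = FALSE)
  if (!isTRUE(all.equal(model$alpha, dataset$alpha))) {
    stop(sprintf("dataset was filtered at alpha = %g but the model uses alpha = %g",
                 dataset$alpha, model$alpha), call. = FALSE)
  }
  net <- model$network
  stopifnot(inherits(net, "conv_net"))
  X <- dataset$inputs
  Tg <- dataset$targets
  n <- ncol(X)
  Vr <- model_retained_basis(model)
  vel <- lapply(net$params, function(p) list(W = p$W * 0, b = p$b * 0))
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 3L, epoch), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (idx in batches) {
      B <- length(idx)
      Xb <- X[, idx, drop = FALSE]
      fwd <- conv_net_forward(net, matrix(as.vector(Xb), ncol = 1L), B,
                              keep_cache = TRUE)
      Z <- matrix(fwd$y, nrow(Xb), B)
      corr <- Z - as.matrix(Vr %*% crossprod(Vr, Z))
      resid <- Xb + corr - Tg[, idx, drop = FALSE]
      loss <- mean(colSums(abs(resid)))
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss * B
      # optimizer normalization: gradient of the per-entry mean absolute
      # error (same minimizer as the per-image sum; the step sizes the
      # default learning rate and momentum assume)
      dcorr <- sign(resid) / (B * nrow(X))
      dZ <- dcorr - as.matrix(Vr %*% crossprod(Vr, dcorr))
      grads <- conv_net_backward(net, fwd$caches, matrix(as.vector(dZ), ncol = 1L), B)
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g$W^2) + sum(g$b^2), 0)))
      scale <- if (gnorm > config$clip_norm) config$clip_norm / gnorm else 1
      for (nm in names(net$params)) {
        vel[[nm]]$W <- config$momentum * vel[[nm]]$W -
          config$learning_rate * scale * grads[[nm]]$W
        vel[[nm]]$b <- config$momentum * vel[[nm]]$b -
          config$learning_rate * scale * grads[[nm]]$b
        net$params[[nm]]$W <- net$params[[nm]]$W + vel[[nm]]$W
        net$params[[nm]]$b <- net$params[[nm]]$b + vel[[nm]]$b
      }
    }
    losses[epoch] <- epoch_loss / n
  }
  net$lipschitz_estimate <- lipschitz_estimate(net, dim = nrow(X),
                                               n_pairs = 20L,
                                               seed = derive_seed(config$seed, 4L, 1L))
  model$network <- net
  list(model = model, loss = losses)
}

#' Train a family of RegNets over an alpha grid
#'
#' One independent training run per regularization parameter: for each
#' `alpha`, the dataset inputs are re-filtered to `B_alpha y^(k)`, a fresh
#' network is initialized from the run seed and trained with
#' [train_regnet()].
#'
#' @param system A `spectral_system`.
#' @param filter A [filter_spec()] (truncated SVD for the learned modes).
#' @param alpha_grid Strictly decreasing positive values.
#' @param dataset A [make_dataset()] result (any alpha; re-filtered per run).
#' @param config A [training_config()]; run `r` uses seed
#'   `derive_seed(config$seed, 5, r)`.
#' @param mode `"continued_svd"` or `"null_space"`.
#' @param base_channels,scales Network architecture, passed to [conv_net()].
#' @return List of training results (each with `model` and `loss`), one per
#'   alpha, in grid order.
#' @export
train_alpha_family <- function(system, filter, alpha_grid, dataset,
                               config = training_config(),
                               mode = c("continued_svd", "null_space"),
                               base_channels = 16L, scales = 3L) {
  mode <- match.arg(mode)
  stopifnot(length(alpha_grid) >= 1L, all(alpha_grid > 0))
  if (length(alpha_grid) > 1L) stopifnot(all(diff(alpha_grid) < 0))
  lapply(seq_along(alpha_grid), function(r) {
    alpha <- alpha_grid[r]
    ds <- refilter_dataset(dataset, system, filter, alpha)
    run_seed <- derive_seed(config$seed, 5L, r)
    net <- conv_net(ds$grid_n, base_channels = base_channels, scales = scales,
                    seed = run_seed)
    mdl <- regnet_model(system, filter, alpha, network = net, mode = mode)
    cfg <- config
    cfg$seed <- run_seed
    train_regnet(mdl, ds, cfg)
  })
}
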