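# End-to-end experiment driver: rescaled error metrics, regularization
# parameter selection on held-out samples, and the full
# train-all-methods / evaluate-on-test protocol.

#' Min-max rescale an image to [0, 1]
#'
#' Affine rescale to the unit interval; constant images (degenerate range)
#' map to all zeros.
#'
#' @param image Numeric matrix or vector.
#' @return Same shape, values in `[0, 1]`.
#' @export
rescale_unit <- function(image) {
  stopifnot(all(is.finite(image)))
  rng <- range(image)
  if (rng[2L] - rng[1L] <= .Machine$double.eps * max(abs(rng), 1)) {
    return(image * 0)
  }
  (image - rng[1L]) / (rng[2L] - rng[1L])
}

#' Rescaled MSE/MAE evaluation of reconstructions
#'
#' Each reconstruction and each ground truth is min-max rescaled to `[0, 1]`
#' independently, then the per-image mean squared error and mean absolute
#' error (means over entries) are averaged over the set.
#'
#' @param reconstructions,truths `d x n` matrices, one image per column.
#' @return A one-row data frame with `mse`, `mae`, `n`.
#' @export
evaluate_reconstructions <- function(reconstructions, truths) {
  R <- as.matrix(reconstructions)
  Tg <- as.matrix(truths)
  if (!identical(dim(R), dim(Tg))) {
    stop("reconstruction and truth sets are misaligned", call. = FALSE)
  }
  mse <- mae <- numeric(ncol(R))
  for (k in seq_len(ncol(R))) {
    a <- rescale_unit(R[, k])
    b <- rescale_unit(Tg[, k])
    mse[k] <- mean((a - b)^2)
    mae[k] <- mean(abs(a - b))
  }
  data.frame(mse = mean(mse), mae = mean(mae), n = ncol(R))
}

#' Select the regularization parameter by validation MSE
#'
#' Simulates a small set of seeded validation phantoms at noise level
#' `delta`, reconstructs each with every candidate model, and returns the
#' candidate whose mean rescaled MSE is minimal; ties break toward the
#' larger alpha (stronger regularization).
#'
#' @param models List of [regnet_model()]s sharing a system (candidates; any
#'   modes), ordered by decreasing `alpha`.
#' @param delta Validation noise level.
#' @param seed Master seed for validation phantoms and noise (streams
#'   distinct from [make_dataset()]'s).
#' @param n_val Number of validation samples (default 10).
#' @return List with `alpha`, `retained` (count of `sigma_n^2 >= alpha`),
#'   `index`, and the per-candidate `table` (data frame of alpha, retained,
#'   mse).
#' @export
select_alpha <- function(models, delta, seed = 1L, n_val = 10L) {
  stopifnot(length(models) >= 1L)
  sys <- models[[1L]]$system
  geometry <- attr(sys$matrix, "geometry")
  if (is.null(geometry)) stop("system carries no projection geometry", call. = FALSE)
  truths <- matrix(0, sys$d, n_val)
  sinos <- matrix(0, sys$m, n_val)
  for (k in seq_len(n_val)) {
    ph <- generate_phantom(derive_seed(seed, 7L, k), geometry)
    sg <- simulate_data(sys, ph, delta, derive_seed(seed, 8L, k))
    truths[, k] <- image_to_vec(ph$coefficients)
    sinos[, k] <- sg$data
  }
  alphas <- vapply(models, function(mdl) mdl$alpha, 0)
  mses <- vapply(models, function(mdl) {
    evaluate_reconstructions(regnet_reconstruct(mdl, sinos), truths)$mse
  }, 0)
  best <- order(mses, -alphas)[1L]   # ties toward larger alpha
  sv <- sys$singular_values
  list(alpha = alphas[best], retained = retained_count(sv, alphas[best]),
       index = best,
       table = data.frame(alpha = alphas,
                          retained = vapply(alphas, function(a) retained_count(sv, a), 0L),
                          mse = mses))
}

#' Configuration for the full reconstruction experiment
#'
#' Defaults describe the desk-scale study: a 32x32 blob grid, 10 angles,
#' 48 offsets, 100 training and 25 test phantoms, truncated SVD with a
#' logarithmic alpha grid over the singular spectrum, evaluation at relative
#' noise levels 0.02 and 0.05.
#'
#' @param geometry A [projection_geometry()].
#' @param alpha_grid Decreasing positive values; `NULL` picks
#'   `n_alpha` values logarithmically spaced over the central part of the
#'   squared singular spectrum once the operator is built.
#' @param n_alpha Number of automatic alpha values (default 5).
#' @param n_train,n_test Training / test set sizes.
#' @param delta_eval Evaluation noise levels.
#' @param train Training configuration ([training_config()]).
#' @param base_channels,scales Network architecture.
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = projection_geometry(grid_n = 32L,
                                                             n_angles = 10L,
                                                             n_offsets = 48L),
                              alpha_grid = NULL, n_alpha = 6L,
                              n_train = 100L, n_test = 25L,
                              delta_eval = c(0.02, 0.05),
                              train = training_config(epochs = 100L),
                              base_channels = 8L, scales = 3L,
                              seed = 1L) {
  structure(list(geometry = geometry, alpha_grid = alpha_grid,
                 n_alpha = as.integer(n_alpha),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 delta_eval = delta_eval, train = train,
                 base_channels = as.integer(base_channels),
                 scales = as.integer(scales), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full sparse-view reconstruction experiment
#'
#' Builds the Radon operator and its singular system, assembles the seeded
#' training set from noise-free data, trains a continued-SVD family and a
#' null-space family over the alpha grid, and evaluates truncated SVD and
#' both learned methods on a held-out test set at every evaluation noise
#' level. Fully reproducible from `(config, config$seed)`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: writes `metrics.csv`, per-run loss
#'   curves and a manifest with the config hash.
#' @param verbose Print stage progress.
#' @return List with `metrics` (data frame: method, alpha, retained, delta,
#'   mse, mae), `best` (per method and delta, the row at the MSE-optimal
#'   alpha), `system`, `models`, `losses`, `config`, `config_hash`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  say("building operator (%d x %d grid) ...", config$geometry$grid_n, config$geometry$grid_n)
  A <- build_operator(config$geometry)
  system <- svd_decompose(A)
  filter <- filter_spec("tsvd")
  sv <- system$singular_values
  alpha_grid <- config$alpha_grid
  if (is.null(alpha_grid)) {
    pos <- sv[positive_mask(system)]^2
    qs <- exp(seq(log(stats::quantile(pos, 0.9)), log(stats::quantile(pos, 0.05)),
                  length.out = config$n_alpha))
    alpha_grid <- as.numeric(qs)
  }
  stopifnot(all(diff(alpha_grid) < 0))

  say("simulating %d training phantoms ...", config$n_train)
  dataset <- make_dataset(system, filter, alpha_grid[1L], config$n_train,
                          seed = config$seed, delta_train = 0)

  say("training %d continued-SVD and %d null-space networks ...",
      length(alpha_grid), length(alpha_grid))
  fams <- list(
    continued_svd = train_alpha_family(system, filter, alpha_grid, dataset,
                                       config$train, mode = "continued_svd",
                                       base_channels = config$base_channels,
                                       scales = config$scales),
    null_space = train_alpha_family(system, filter, alpha_grid, dataset,
                                    config$train, mode = "null_space",
                                    base_channels = config$base_channels,
                                    scales = config$scales)
  )
  models <- list(
    tsvd = lapply(alpha_grid, function(a) regnet_model(system, filter, a, mode = "plain")),
    continued_svd = lapply(fams$continued_svd, `[[`, "model"),
    null_space = lapply(fams$null_space, `[[`, "model")
  )
  losses <- lapply(fams, function(f) lapply(f, `[[`, "loss"))

  say("simulating %d test phantoms ...", config$n_test)
  test_seed <- derive_seed(config$seed, 9L, 1L)
  geometry <- config$geometry
  truths <- matrix(0, system$d, config$n_test)
  clean <- matrix(0, system$m, config$n_test)
  for (k in seq_len(config$n_test)) {
    ph <- generate_phantom(derive_seed(test_seed, 1L, k), geometry)
    truths[, k] <- image_to_vec(ph$coefficients)
    clean[, k] <- apply_forward(system, truths[, k])
  }

  rows <- list()
  for (delta in config$delta_eval) {
    sinos <- clean
    if (delta > 0) {
      for (k in seq_len(config$n_test)) {
        scale <- max(abs(clean[, k]))
        xi <- with_seed(derive_seed(test_seed, 2L, k), rnorm(system$m, 0, scale))
        sinos[, k] <- clean[, k] + delta * xi
      }
    }
    for (method in names(models)) {
      for (j in seq_along(alpha_grid)) {
        mdl <- models[[method]][[j]]
        ev <- evaluate_reconstructions(regnet_reconstruct(mdl, sinos), truths)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, alpha = alpha_grid[j],
          retained = retained_count(sv, alpha_grid[j]),
          delta = delta, mse = ev$mse, mae = ev$mae, n_test = ev$n,
          seed = config$seed)
      }
    }
    say("evaluated delta = %g", delta)
  }
  metrics <- do.call(rbind, rows)

  best <- do.call(rbind, lapply(split(metrics, list(metrics$method, metrics$delta)),
                                function(df) df[order(df$mse, -df$alpha)[1L], ]))
  rownames(best) <- NULL

  out <- list(metrics = metrics, best = best, system = system, models = models,
              losses = losses, alpha_grid = alpha_grid, config = config,
              config_hash = config_hash(config[setdiff(names(config), "train")]),
              elapsed = as.numeric(Sys.time() - t0, units = "secs"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    metrics$config_hash <- out$config_hash
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    for (method in names(losses)) {
      for (j in seq_along(losses[[method]])) {
        write.csv(data.frame(epoch = seq_along(losses[[method]][[j]]),
                             loss = losses[[method]][[j]],
                             alpha = alpha_grid[j], config_hash = out$config_hash),
                  file.path(out_dir, sprintf("loss_%s_alpha%02d.csv", method, j)),
                  row.names = FALSE)
      }
    }
  }
  out
}

#' Export a coefficient image as PNG
#'
#' Min-max scaled 8-bit export for visual inspection (requires the `png`
#' package).
#'
#' @param image `n x n` coefficient matrix (or vector of length `n^2`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("package 'png' is required for PNG export", call. = FALSE)
  }
  if (is.null(dim(image))) image <- vec_to_image(image, as.integer(sqrt(length(image))))
  scaled <- rescale_unit(image)
  # transpose so the first image axis is horizontal
  png::writePNG(t(scaled)[nrow(scaled):1, , drop = FALSE], target = path)
  invisible(path)
}
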