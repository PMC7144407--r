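# Seeded Shepp-Logan-type phantoms, sinogram simulation with the
# amplitude-scaled Gaussian noise model, and training/test dataset assembly.

#' Generate a random Shepp-Logan-type coefficient phantom
#'
#' Draws a random superposition of ellipses in the Shepp-Logan style: one
#' enclosing "skull" ellipse of intensity 1 plus interior ellipses with
#' mixed-sign lower intensities, and evaluates the sum at the blob-grid
#' centres to obtain the coefficient image. Generation is bit-identical per
#' `(seed, geometry, complexity)`.
#'
#' Randomization ranges (configurable only through `complexity` here; the
#' style itself is fixed): interior centres inside the disk of radius 0.75,
#' semi-axes 0.05-0.6 (shrunk so every ellipse stays inside the unit
#' square), rotations uniform, intensities uniform on `[-1, 1]`. The
#' coefficient image is clamped to `[-2, 2]` so the sinogram sup-norm used by
#' the noise model is always well-behaved.
#'
#' @param seed Non-negative integer seed.
#' @param geometry A [projection_geometry()] (supplies the coefficient grid).
#' @param complexity Integer range `c(lo, hi)` for the total ellipse count
#'   (default `c(5, 12)`).
#' @return An object of class `phantom`: fields `ellipses` (data frame),
#'   `coefficients` (`grid_n x grid_n` matrix) and `seed`.
#' @export
generate_phantom <- function(seed, geometry, complexity = c(5L, 12L)) {
  stopifnot(seed >= 0, inherits(geometry, "projection_geometry"),
            length(complexity) == 2L, complexity[1L] >= 1L,
            complexity[2L] >= complexity[1L])
  with_seed(seed, {
    n_ell <- if (complexity[1L] == complexity[2L]) complexity[1L] else
      sample(seq.int(complexity[1L], complexity[2L]), 1L)
    # enclosing skull ellipse, intensity fixed at 1
    ells <- data.frame(
      cx = runif(1, -0.04, 0.04), cy = runif(1, -0.04, 0.04),
      ax = runif(1, 0.60, 0.74), ay = runif(1, 0.80, 0.92),
      rot = runif(1, -0.15, 0.15), intensity = 1
    )
    if (n_ell > 1L) {
      for (i in seq_len(n_ell - 1L)) {
        rad <- 0.75 * sqrt(runif(1))
        ang <- runif(1, 0, 2 * pi)
        cx <- rad * cos(ang); cy <- rad * sin(ang)
        ax_max <- max(0.06, min(0.6, 0.98 - sqrt(cx^2 + cy^2)))
        ells <- rbind(ells, data.frame(
          cx = cx, cy = cy,
          ax = runif(1, 0.05, ax_max), ay = runif(1, 0.05, ax_max),
          rot = runif(1, 0, pi), intensity = runif(1, -1, 1)
        ))
      }
    }
    ax <- geometry_axes(geometry)
    img <- ellipse_sum(ax$centers, ells)
    img <- pmin(pmax(img, -2), 2)
    structure(list(ellipses = ells,
                   coefficients = vec_to_image(img, geometry$grid_n),
                   seed = as.integer(seed), geometry = geometry),
              class = "phantom")
  })
}

# evaluate a sum of ellipse indicators at 2-column point matrix
ellipse_sum <- function(points, ellipses) {
  val <- numeric(nrow(points))
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    dx <- points[, 1L] - e$cx
    dy <- points[, 2L] - e$cy
    u <- dx * cos(e$rot) + dy * sin(e$rot)
    v <- -dx * sin(e$rot) + dy * cos(e$rot)
    val <- val + e$intensity * as.numeric((u / e$ax)^2 + (v / e$ay)^2 <= 1)
  }
  val
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed %d, %d ellipses, %d x %d coefficients in [%.3g, %.3g]\n",
              x$seed, nrow(x$ellipses), nrow(x$coefficients), ncol(x$coefficients),
              min(x$coefficients), max(x$coefficients)))
  invisible(x)
}

#' Simulate sinogram data with amplitude-scaled Gaussian noise
#'
#' Computes `y = A c + delta * xi` with `xi_j` i.i.d. Gaussian of mean zero
#' and standard deviation `|A c|_inf` (the sup norm of the clean sinogram),
#' so `delta` is a relative noise level. The clean sinogram is stored and
#' `delta = 0` returns it exactly.
#'
#' @param system A `spectral_system` built from a Radon operator (or any
#'   forward matrix matching the phantom grid).
#' @param phantom A [generate_phantom()] result.
#' @param delta Relative noise level `>= 0`.
#' @param noise_seed Integer seed for the noise draw.
#' @return An object of class `sinogram`: `data`, `clean_reference`,
#'   `noise_level`, `noise_seed`.
#' @export
simulate_data <- function(system, phantom, delta = 0, noise_seed = 0L) {
  stopifnot(inherits(phantom, "phantom"), delta >= 0)
  cvec <- image_to_vec(phantom$coefficients)
  if (length(cvec) != system$d) {
    stop(sprintf("phantom grid (%d coefficients) does not match operator domain (d = %d)",
                 length(cvec), system$d), call. = FALSE)
  }
  clean <- apply_forward(system, cvec)
  data <- if (delta > 0) {
    scale <- max(abs(clean))
    clean + delta * with_seed(noise_seed, rnorm(length(clean), mean = 0, sd = scale))
  } else clean
  structure(list(data = data, clean_reference = clean,
                 noise_level = delta, noise_seed = as.integer(noise_seed)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d samples, delta = %g (seed %d)\n",
              length(x$data), x$noise_level, x$noise_seed))
  invisible(x)
}

#' Assemble a paired training/test dataset
#'
#' Generates `n_samples` seeded phantoms, simulates their sinograms at noise
#' level `delta_train` (default 0: networks are trained on noise-free data),
#' and pairs each regularized reconstruction `B_alpha y^(k)` with its
#' ground-truth coefficient image. Per-sample seeds are derived from the
#' master `seed` by a counter scheme, so regeneration is exact.
#'
#' @param system A `spectral_system` of the forward operator.
#' @param filter A [filter_spec()].
#' @param alpha Positive regularization parameter used for the inputs.
#' @param n_samples Number of pairs.
#' @param seed Master seed.
#' @param delta_train Noise level for the simulated training data (default 0).
#' @param complexity Ellipse-count range passed to [generate_phantom()].
#' @return An object of class `regnet_dataset`: `inputs` (`d x n` matrix of
#'   `B_alpha y` columns), `targets` (`d x n` ground-truth coefficients),
#'   `sinograms` (`m x n` simulated data, for re-filtering at other alphas),
#'   plus `alpha`, `filter_name`, `seed`, `grid_n`.
#' @export
make_dataset <- function(system, filter, alpha, n_samples, seed,
                         delta_train = 0, complexity = c(5L, 12L)) {
  stopifnot(n_samples >= 1)
  geometry <- attr(system$matrix, "geometry")
  if (is.null(geometry)) {
    stop("`system` carries no projection geometry; build it from build_operator()",
         call. = FALSE)
  }
  targets <- matrix(0, system$d, n_samples)
  sinos <- matrix(0, system$m, n_samples)
  for (k in seq_len(n_samples)) {
    ph <- generate_phantom(derive_seed(seed, 1L, k), geometry, complexity)
    sg <- simulate_data(system, ph, delta_train, derive_seed(seed, 2L, k))
    targets[, k] <- image_to_vec(ph$coefficients)
    sinos[, k] <- sg$data
  }
  structure(list(inputs = filter_inputs(system, filter, alpha, sinos),
                 targets = targets, sinograms = sinos,
                 alpha = alpha, filter_name = filter$name,
                 seed = as.integer(seed), delta_train = delta_train,
                 grid_n = geometry$grid_n),
            class = "regnet_dataset")
}

# regularized reconstructions for all sinogram columns at once
filter_inputs <- function(system, filter, alpha, sinos) {
  sv <- system$singular_values
  g <- filter$g(sv^2, alpha)
  coef <- crossprod(system$range_basis, sinos)
  as.matrix(system$domain_basis %*% (g * sv * coef))
}

#' Recompute dataset inputs at a different regularization parameter
#'
#' Re-filters the stored sinograms with `B_alpha` for a new `alpha`, leaving
#' targets and pairing untouched.
#'
#' @param dataset A `regnet_dataset`.
#' @param system,filter,alpha As in [make_dataset()].
#' @return The dataset with updated `inputs` and `alpha`.
#' @export
refilter_dataset <- function(dataset, system, filter, alpha) {
  stopifnot(inherits(dataset, "regnet_dataset"))
  dataset$inputs <- filter_inputs(system, filter, alpha, dataset$sinograms)
  dataset$alpha <- alpha
  dataset$filter_name <- filter$name
  dataset
}

#' @export
print.regnet_dataset <- function(x, ...) {
  cat(sprintf("<regnet_dataset> %d pairs on %d x %d grid, %s filter, alpha = %g, seed %d\n",
              ncol(x$inputs), x$grid_n, x$grid_n, x$filter_name, x$alpha, x$seed))
  invisible(x)
}
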