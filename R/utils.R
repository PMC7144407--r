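# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Canonical reshape between coefficient vectors and grid images
#'
#' All modules use one convention: a coefficient vector of length `n^2` maps to
#' an `n x n` matrix column-by-column (R's native order), and back with
#' `as.vector()`. Basis-centre `i` of the imaging grid corresponds to matrix
#' entry `[ (i-1) %% n + 1, (i-1) %/% n + 1 ]`.
#'
#' @param v Numeric vector of length `n^2`.
#' @param n Grid side length.
#' @return `vec_to_image()`: an `n x n` matrix; `image_to_vec()`: a vector.
#' @export
vec_to_image <- function(v, n) {
  stopifnot(length(v) == n * n)
  matrix(v, nrow = n, ncol = n)
}

#' @rdname vec_to_image
#' @param img An `n x n` matrix.
#' @export
image_to_vec <- function(img) {
  as.vector(img)
}

# Euclidean norm
l2norm <- function(x) sqrt(sum(x^2))

# FNV-1a hash of an R object's deparsed form; cheap provenance tag for
# configs and artifacts (no cryptographic intent).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Counter-based child seeds: distinct, reproducible streams per sample,
# kept below 2^31.
derive_seed <- function(master, stream, k) {
  (as.integer(master) + 1000003L * as.integer(stream) + as.integer(k)) %% 2147483647L
}
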