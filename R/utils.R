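# Internal numeric / RNG helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Folds a master seed and an arbitrary sequence of integer labels (cell
#' coordinates, dataset index, ...) into a new seed in `[1, 2^31 - 2]` by a
#' multiplicative-congruential hash. Distinct label sequences give distinct
#' streams; the same labels always give the same seed.
#'
#' @param master integer master seed.
#' @param ... integer-like labels identifying the consumer.
#' @return single integer seed.
#' @export
derive_seed <- function(master, ...) {
  labs <- c(as.numeric(master), vapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else as.numeric(x)
  }, numeric(1)))
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- 104729
  for (v in labs) {
    # double arithmetic is exact here: intermediates stay below 2^53
    h <- (h * 48271 + (abs(v) %% m) + 1) %% m
    h <- (h * 16807) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

## small vector helpers ------------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

# row-wise euclidean norms of a matrix
row_norms <- function(m) sqrt(rowSums(m^2))

# rotation matrix about arbitrary unit axis (Rodrigues), angle in degrees
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
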