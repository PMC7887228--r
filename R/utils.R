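# Small internal helpers shared across modules. All vectorized helpers operate
# on n x 3 matrices of row vectors.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

## rowwise cross product of n x 3 matrices
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a * a))

row_unit <- function(a) {
  n <- row_norm(a)
  if (any(n < 1e-12)) stop("cannot normalize zero-length vector")
  a / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

## Rodrigues rotation of row vectors v about unit axes k by angles theta
rotate_about <- function(v, k, theta) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  if (is.null(dim(k))) k <- matrix(k, nrow = nrow(v), ncol = 3, byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  v * ct + row_cross(k, v) * st + k * row_dot(k, v) * (1 - ct)
}

## circular (0-based spec convention -> 1-based R) index helper
cyc <- function(i, n) ((i - 1) %% n) + 1

## Run computation with a private RNG state; never touches the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
}
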