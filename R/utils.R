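# Small 3-vector helpers shared across the kinematics code.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v, tol = 1e-12) {
  n <- vec_norm(v)
  if (n < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise versions operating on n x 3 matrices (used per-frame).
rows_norm <- function(m) sqrt(rowSums(m * m))

rows_unit <- function(m, tol = 1e-12) {
  n <- rows_norm(m)
  if (any(n < tol)) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  m / n
}

rows_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

deg <- function(rad) rad * 180 / pi
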