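# Small geometry helpers shared across modules. All positions are world mm.

vec_norm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Deterministic unit vector perpendicular to d: orthogonalize the world axis
# least aligned with d (lowest axis index on ties).
perp_vector <- function(d) {
  d <- normalize(d)
  ax <- which.min(abs(d))
  e <- c(0, 0, 0)
  e[ax] <- 1
  normalize(e - sum(e * d) * d)
}

# Angle between two vectors, degrees in [0, 180).
angle_deg <- function(a, b) {
  na <- vec_norm(a); nb <- vec_norm(b)
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  ct <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Row-wise squared distances from points (n x 3) to a single point.
rowdist2 <- function(pts, p) {
  (pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2 + (pts[, 3L] - p[3L])^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
}
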