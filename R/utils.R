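# Small 3-vector helpers shared across the geometry and metrics code.
# All coordinates are millimetres, all angles degrees unless stated.

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x))) {
    stop("expected a finite 3-vector, got length ", length(x), call. = FALSE)
  }
  x
}

norm3 <- function(x) sqrt(sum(x * x))

normalize3 <- function(x, what = "vector") {
  n <- norm3(x)
  if (n < 1e-12) stop("cannot normalize near-zero ", what, call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Angle between two vectors via atan2(|a x b|, a . b): stable at 0 and 180
# degrees, never NaN from arccos round-off.
angle_between_deg <- function(a, b) {
  cr <- cross3(a, b)
  atan2(norm3(cr), sum(a * b)) * 180 / pi
}

# Rodrigues rotation of the rows of `p` (n x 3) about unit axis `k` by
# `theta_deg`.
rotate_about_axis <- function(p, k, theta_deg) {
  k <- normalize3(vec3(k), "rotation axis")
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  p <- as_point_matrix(p)
  kx <- p[, 1L] * k[1L] + p[, 2L] * k[2L] + p[, 3L] * k[3L]
  cp <- cbind(k[2L] * p[, 3L] - k[3L] * p[, 2L],
              k[3L] * p[, 1L] - k[1L] * p[, 3L],
              k[1L] * p[, 2L] - k[2L] * p[, 1L])
  p * ct + cp * st + outer(kx * (1 - ct), k)
}

as_point_matrix <- function(p, what = "points") {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L, byrow = TRUE)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop(what, " must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(p))) stop(what, " contain non-finite coordinates", call. = FALSE)
  dimnames(p) <- NULL
  p
}

# Random 3D rotation matrix (uniform over SO(3)) -- used by tests and the
# rigid-invariance checks.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4L)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}
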