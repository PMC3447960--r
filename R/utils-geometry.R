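#' @importFrom stats quantile rnorm runif sd setNames
#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble as_tibble tibble
#' @importFrom utils head tail
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-15) abort("cannot normalise a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle_deg`
#' degrees about the (normalised) `axis`.
#'
#' @param axis numeric length-3 axis of rotation (any non-zero length).
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 orthonormal rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vector(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Orthonormal basis of the plane perpendicular to v (columns e1, e2).
perpendicular_basis <- function(v) {
  v <- unit_vector(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(ref - sum(ref * v) * v)
  e2 <- c(
    v[2] * e1[3] - v[3] * e1[2],
    v[3] * e1[1] - v[1] * e1[3],
    v[1] * e1[2] - v[2] * e1[1]
  )
  cbind(e1, e2)
}

# Uniformly random rotation matrix (Arvo's method via quaternion).
random_rotation <- function() {
  u <- runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Near-uniform point set on the unit sphere
#'
#' Spherical Fibonacci lattice with the offset mapping
#' `z_k = 1 - (2k + 1)/n`, which gives good minimum-separation behaviour
#' for n >= 3. `n = 1` returns the north pole and `n = 2` the two poles,
#' since the offset lattice does not place two points antipodally.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  if (n == 2) return(matrix(c(0, 0, 1, 0, 0, -1), 2, 3, byrow = TRUE))
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  cbind(r * cos(phi), r * sin(phi), z)
}

coords_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  stopifnot(all(c("x", "y", "z") %in% names(x)))
  unname(cbind(x$x, x$y, x$z))
}

# largest-remainder integer allocation of `total` across `fractions`
largest_remainder <- function(total, fractions) {
  stopifnot(total >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must sum to 1")
  }
  exact <- total * fractions
  counts <- floor(exact)
  short <- total - sum(counts)
  if (short > 0) {
    order_rem <- order(exact - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}
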