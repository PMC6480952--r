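# Small 3D vector helpers used throughout the coarse-grain and geometry code.
# All vectors are plain numeric length-3; matrices are n x 3 with one point
# per row.

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two 3D vectors
#'
#' Returns the unsigned angle in degrees in \code{[0, 180]}.  An angle of
#' 180 degrees means anti-aligned vectors, the geometry of a coaxial stack
#' when both stem vectors point away from the connecting loop.
#'
#' @param a,b numeric length-3 vectors; both must be nonzero.
#' @return angle in degrees.
#' @export
#' @examples
#' vec_angle(c(0, 0, 1), c(0, 0, -1))  # 180
#' vec_angle(c(1, 0, 0), c(0, 1, 0))   # 90
vec_angle <- function(a, b) {
  na <- vec_norm(a); nb <- vec_norm(b)
  if (na < 1e-12 || nb < 1e-12) stop("vec_angle: zero vector")
  ct <- sum(a * b) / (na * nb)
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

# Rotation matrix mapping unit vector `from` onto unit vector `to`
# (Rodrigues).  Deterministic choice of the perpendicular when the vectors
# are anti-parallel.
rotation_between <- function(from, to) {
  f <- vec_unit(from); t <- vec_unit(to)
  v <- vec_cross(f, t)
  c_ <- sum(f * t)
  if (vec_norm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # pick any axis orthogonal to f
    ax <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- vec_unit(vec_cross(f, ax))
    return(rotation_about(ax, pi))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

# Rotation about a unit axis by `theta` radians.
rotation_about <- function(axis, theta) {
  u <- vec_unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

# Apply rigid motion (R, t) to an n x 3 coordinate matrix.
transform_points <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(ncol(xyz) == 3)
  sweep(xyz %*% t(R), 2, t, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
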