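# Small 3D vector/matrix helpers shared across modules. All lengths in mm,
# angles in radians internally (degrees only at user-facing interfaces).

vec_norm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps * 100)
    stop("cannot normalize a (near-)zero vector")
  v / n
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula: rotation by `angle` (radians) about the unit direction
#' `axis`, right-handed.
#'
#' @param axis numeric length-3 direction (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  k <- unit_vector(axis)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Any vector not parallel to v, used to seed orthonormal frames.
perpendicular_any <- function(v) {
  v <- unit_vector(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vector(ref - sum(ref * v) * v)
}

# Cumulative chord length of an N x 3 polyline matrix.
cumulative_arc_length <- function(points) {
  n <- nrow(points)
  if (n < 2) return(0)
  d <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-n, , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Shoelace area of a 2D polygon (vertices in order, not repeated); signed,
# positive when counter-clockwise.
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Even-odd point-in-polygon test in 2D.
point_in_polygon <- function(p, xy) {
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  xi <- xy[, 1]; yi <- xy[, 2]
  xj <- xy[j, 1]; yj <- xy[j, 2]
  crosses <- ((yi > p[2]) != (yj > p[2])) &
    (p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi)
  sum(crosses) %% 2 == 1
}
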