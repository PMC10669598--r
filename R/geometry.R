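## Low-level vector geometry and circular (angular) statistics.
## All angles are degrees in (-180, 180]; all coordinates Angstrom.

#' Wrap an angle into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  ## map -180 to +180 so the interval is half-open on the left
  y[y == -180] <- 180
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion of the plane (p1,p2,p3) against (p2,p3,p4),
#' computed with the atan2 formulation, wrapped into (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return dihedral in degrees, (-180, 180].
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b2) < 1e-9) stop("degenerate geometry: p2 == p3")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate geometry: colinear points in dihedral")
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## Dihedral for a 4-row coordinate matrix (rows p1..p4)
dihedral_rows <- function(m) compute_dihedral(m[1, ], m[2, ], m[3, ], m[4, ])

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric 3-vector (need not be unit length).
#' @param angle rotation angle, degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  c1 <- cos(th); s1 <- sin(th); t1 <- 1 - c1
  x <- u[1]; y <- u[2]; z <- u[3]
  matrix(c(
    t1 * x * x + c1,      t1 * x * y - s1 * z,  t1 * x * z + s1 * y,
    t1 * x * y + s1 * z,  t1 * y * y + c1,      t1 * y * z - s1 * x,
    t1 * x * z - s1 * y,  t1 * y * z + s1 * x,  t1 * z * z + c1),
    nrow = 3, byrow = TRUE)
}

## Rotation matrix mapping unit vector a onto unit vector b
align_rotation <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  c1 <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c1 > 0) return(diag(3))
    ## opposite vectors: rotate 180 about any perpendicular
    p <- cross3(a, c(1, 0, 0))
    if (vnorm(p) < 1e-6) p <- cross3(a, c(0, 1, 0))
    return(rotation_matrix(p, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               nrow = 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c1))
}

## Unit quaternion (w,x,y,z) to rotation matrix
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3, byrow = TRUE)
}

## Uniform random unit quaternion (Shoemake); component order is
## immaterial for uniformity, returned as (w,x,y,z)
random_quaternion <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

## Quaternion for a rotation of `angle` degrees about random axis
small_rotation_quaternion <- function(angle_sd) {
  ax <- stats::rnorm(3)
  while (vnorm(ax) < 1e-8) ax <- stats::rnorm(3)
  ang <- deg2rad(stats::rnorm(1, 0, angle_sd)) / 2
  c(cos(ang), sin(ang) * unit(ax))
}

## rotation matrix -> unit quaternion (w,x,y,z), Shepperd's method
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q * q))
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

## NeRF atom placement: position D such that |CD| = bond,
## angle(B,C,D) = angle deg, dihedral(A,B,C,D) = torsion deg.
place_atom <- function(a, b, c1, bond, angle, torsion) {
  bc <- unit(c1 - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- deg2rad(180 - angle)
  ph <- deg2rad(torsion)
  d2 <- bond * c(cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c1 + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Circular mean of angles
#'
#' @param x angles in degrees.
#' @return mean direction in degrees, (-180, 180]; NA for empty input.
#' @export
circular_mean <- function(x) {
  if (length(x) == 0) return(NA_real_)
  r <- deg2rad(x)
  wrap_angle(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Circular standard deviation of angles (degrees)
#' @param x angles in degrees.
#' @export
circular_sd <- function(x) {
  if (length(x) < 2) return(NA_real_)
  r <- deg2rad(x)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(max(rbar, 1e-12), 1)
  rad2deg(sqrt(-2 * log(rbar)))
}

## Smallest absolute circular difference, in [0, 180]
circular_dist <- function(a, b) abs(wrap_angle(a - b))
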