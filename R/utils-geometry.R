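# Small geometric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about a coordinate axis
#'
#' Active right-handed rotation by `angle` degrees about the x, y or z axis.
#'
#' @param angle Rotation angle in degrees.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return A 3x3 orthogonal matrix.
#' @keywords internal
rot_axis <- function(angle, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  a <- deg2rad(angle)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE)
  )
}

#' ZYZ Euler rotation matrix
#'
#' Active rotation `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`, the convention
#' used for principal-axis-frame orientations throughout the package.
#'
#' @param alpha,beta,gamma Euler angles in degrees.
#' @return A 3x3 rotation matrix whose columns are the principal axes
#'   expressed in the laboratory frame.
#' @export
rot_zyz <- function(alpha, beta, gamma) {
  rot_axis(alpha, "z") %*% rot_axis(beta, "y") %*% rot_axis(gamma, "z")
}

#' Extract ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [rot_zyz()]. For `beta` near 0 or 180 degrees only the sum
#' (difference) of `alpha` and `gamma` is determined; the canonical choice
#' `gamma = 0` is returned.
#'
#' @param R A 3x3 rotation matrix.
#' @return Named numeric vector `c(alpha, beta, gamma)` in degrees.
#' @export
euler_zyz <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == 3))
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(sin(beta)) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    if (cb < 0) alpha <- -alpha
    gamma <- 0
  }
  c(alpha = rad2deg(alpha), beta = rad2deg(beta), gamma = rad2deg(gamma))
}

# Rotation matrix taking unit vector `from` onto unit vector `to`
# (Rodrigues construction; identity when already aligned).
rot_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  cth <- sum(from * to)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to `from`
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * from) * from
    axis <- axis / sqrt(sum(axis^2))
    return(2 * tcrossprod(axis) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

# Angle (degrees) of the rotation encoded by matrix R.
rotation_angle_deg <- function(R) {
  tr <- sum(diag(R))
  rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
}
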