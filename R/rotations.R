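# Rotation algebra and the Cardan angle convention used throughout.
#
# Segment frames are right-handed with the x-axis pointing laterally, the
# y-axis anteriorly and the z-axis proximally.  Joint rotations are expressed
# for the tibia relative to the femur as an intrinsic XYZ Cardan sequence:
# alpha_x (extension positive; flexion is a negative rotation about the
# lateral x-axis), beta_y (adduction positive) and gamma_z (internal tibial
# rotation positive).  All public interfaces use degrees; trigonometry is
# done in radians internally.

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

#' Elementary rotation matrices
#'
#' Proper rotations about the x, y or z axis of a right-handed frame.
#'
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return A 3x3 rotation matrix.
#' @examples
#' rot_z(90)
#' @export
rot_x <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0,
           0, ca, -sa,
           0, sa, ca), nrow = 3L, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa,
           0, 1, 0,
           -sa, 0, ca), nrow = 3L, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0,
           sa, ca, 0,
           0, 0, 1), nrow = 3L, byrow = TRUE)
}

#' Test for a proper rotation matrix
#'
#' Checks orthonormality (\eqn{R^T R = I}) and unit determinant within a
#' numerical tolerance.
#'
#' @param R A 3x3 numeric matrix.
#' @param tol Tolerance on orthonormality and determinant (default `1e-9`).
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || !all(is.finite(R)))
    return(FALSE)
  max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, what = "matrix", tol = 1e-8) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || !all(is.finite(R)))
    stop_invalid("%s must be a finite 3x3 matrix", what)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop_invalid("%s is not a proper rotation (orthonormal, det = +1)", what)
  invisible(R)
}

#' Cardan angles to rotation matrix (intrinsic XYZ)
#'
#' Composes \eqn{R = R_x(\alpha) R_y(\beta) R_z(\gamma)}, the intrinsic
#' x-then-y-then-z Cardan sequence (knee extension, tibial adduction,
#' internal tibial rotation).
#'
#' @param angles Numeric length-3 vector `(alpha_x, beta_y, gamma_z)` in
#'   degrees.
#' @return A 3x3 proper rotation matrix.
#' @examples
#' cardan_to_matrix(c(-60, 5, -8))
#' @export
cardan_to_matrix <- function(angles) {
  if (length(angles) != 3L || !all(is.finite(angles)))
    stop_invalid("angles must be three finite values (degrees)")
  rot_x(angles[1L]) %*% rot_y(angles[2L]) %*% rot_z(angles[3L])
}

# Cardan extraction from matrix entries, vectorised over samples.  For the
# intrinsic XYZ sequence:
#   R13 = sin(beta),  R23 = -sin(alpha) cos(beta),  R33 = cos(alpha) cos(beta)
#   R12 = -cos(beta) sin(gamma),  R11 = cos(beta) cos(gamma)
# Gimbal proximity (|cos beta| < gimbal_tol) raises a degenerate-orientation
# condition carrying the gamma = 0 resolution.  Returns an n x 3 matrix in
# degrees.
cardan_from_entries <- function(r11, r12, r13, r21, r22, r23, r33,
                                gimbal_tol = 1e-7) {
  s_beta <- pmin(1, pmax(-1, r13))
  cos_beta <- sqrt(pmax(0, 1 - s_beta^2))
  bad <- which(cos_beta < gimbal_tol)
  if (length(bad)) {
    i <- bad[1L]
    beta <- 90 * sign(s_beta[i])
    alpha <- rad2deg(
      if (s_beta[i] > 0) atan2(r21[i], r22[i]) else atan2(-r21[i], r22[i])
    )
    stop_gimbal(c(alpha, beta, 0), samples = bad)
  }
  cbind(
    alpha_x = rad2deg(atan2(-r23, r33)),
    beta_y  = rad2deg(asin(s_beta)),
    gamma_z = rad2deg(atan2(-r12, r11))
  )
}

#' Rotation matrix to Cardan angles (intrinsic XYZ)
#'
#' Inverse of [cardan_to_matrix()], with `beta_y` on the branch
#' \eqn{[-90, 90]} degrees.  Orientations whose `beta_y` lies within the
#' gimbal tolerance of 90 degrees raise a degenerate-orientation condition
#' (class `reframekin_gimbal_error`) carrying the conventional resolution
#' (`gamma_z = 0`, free rotation folded into `alpha_x`).
#'
#' @param R A 3x3 proper rotation matrix.
#' @param gimbal_tol Threshold on `|cos(beta_y)|` below which the
#'   orientation is treated as degenerate (default `1e-7`).
#' @return Named numeric vector `(alpha_x, beta_y, gamma_z)` in degrees.
#' @examples
#' matrix_to_cardan(cardan_to_matrix(c(-60, 5, -8)))
#' @export
matrix_to_cardan <- function(R, gimbal_tol = 1e-7) {
  assert_rotation(R, "R")
  out <- cardan_from_entries(R[1, 1], R[1, 2], R[1, 3],
                             R[2, 1], R[2, 2], R[2, 3], R[3, 3],
                             gimbal_tol = gimbal_tol)
  c(alpha_x = unname(out[1, 1]), beta_y = unname(out[1, 2]),
    gamma_z = unname(out[1, 3]))
}

#' Relative joint rotation of the tibia with respect to the femur
#'
#' Returns \eqn{R_{fem}^T R_{tib}}, the change of basis taking tibial axes
#' into femoral coordinates; Cardan extraction of this matrix yields the
#' tibio-femoral joint angles.
#'
#' @param femur,tibia 3x3 proper rotation matrices (segment orientations in
#'   a common lab frame).
#' @return A 3x3 proper rotation matrix.
#' @export
joint_rotation <- function(femur, tibia) {
  assert_rotation(femur, "femur")
  assert_rotation(tibia, "tibia")
  crossprod(femur, tibia)
}

#' Report a frame correction as a Cardan triplet
#'
#' Expresses a constant frame re-orientation as an intrinsic Cardan sequence
#' about the raw mediolateral (x), anteroposterior (y) and longitudinal (z)
#' segment axes, in that order — the convention used when reporting frame
#' transformations.
#'
#' @param R_corr A 3x3 proper rotation matrix.
#' @return Named numeric vector `(alpha_x, beta_y, gamma_z)` in degrees.
#' @export
report_transform <- function(R_corr) {
  matrix_to_cardan(R_corr)
}

#' Unwrap an angle series across the +/-180 degree boundary
#'
#' @param x Numeric vector of angles in degrees.
#' @return Unwrapped angles (jumps larger than 180 degrees removed).
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  rad2deg(signal::unwrap(deg2rad(x)))
}

# Mirror matrix for the sagittal plane (x is mediolateral).
.mirror_M <- diag(c(-1, 1, 1))

# Conjugate an orientation (or 3x3xn array of orientations) by the sagittal
# mirror: R -> M R M.  Preserves properness since det(M)^2 = 1.
mirror_orientation <- function(R) {
  if (is.array(R) && length(dim(R)) == 3L) {
    out <- R
    out[1, 2, ] <- -R[1, 2, ]
    out[1, 3, ] <- -R[1, 3, ]
    out[2, 1, ] <- -R[2, 1, ]
    out[3, 1, ] <- -R[3, 1, ]
    out
  } else {
    .mirror_M %*% R %*% .mirror_M
  }
}

#' Mirror left-side data into the right-knee convention
#'
#' Left knees are processed as right knees by inverting the mediolateral
#' (x) coordinate: point coordinates map `x` to `-x`; orientations are
#' conjugated, \eqn{R \mapsto M R M} with \eqn{M = diag(-1, 1, 1)}, which
#' preserves properness.  On joint angles the operation preserves flexion
#' and negates ab/adduction and internal/external rotation.
#'
#' @param x A [pose_series()] flagged as left side, a 3x3 rotation matrix,
#'   a 3x3xn array of orientations, or an n x 3 matrix of point
#'   coordinates (columns x, y, z).
#' @param kind For plain matrices/arrays: `"orientation"` or `"points"`.
#' @return Mirrored object of the same kind; pose series are returned with
#'   the `mirrored` flag set (mirroring an already-mirrored series is an
#'   error).
#' @export
mirror_left_to_right <- function(x, kind = c("orientation", "points")) {
  UseMethod("mirror_left_to_right")
}

#' @export
mirror_left_to_right.default <- function(x, kind = c("orientation", "points")) {
  kind <- match.arg(kind)
  if (kind == "points") {
    if (!is.matrix(x) || ncol(x) != 3L)
      stop_invalid("point coordinates must be an n x 3 matrix")
    x[, 1L] <- -x[, 1L]
    return(x)
  }
  if (is.matrix(x)) assert_rotation(x, "orientation")
  mirror_orientation(x)
}
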