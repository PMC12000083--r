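# Pose and joint-angle series containers.

#' Segment pose series
#'
#' A time series of segment orientations (3x3 proper rotation matrices) for
#' one segment of one knee/trial, together with capture metadata.
#'
#' @param R A 3x3xn array of proper rotation matrices.
#' @param rate_hz Sampling rate in Hz.
#' @param seg Segment label, `"femur"` or `"tibia"`.
#' @param side Knee side, `"R"` or `"L"`.
#' @param mirrored Has a left-side series already been mirrored into the
#'   right-knee convention?
#' @param events Integer sample indices of gait events (cycle boundaries),
#'   strictly increasing.
#' @param time_s Optional sample times in seconds (defaults to
#'   `(0:(n-1))/rate_hz`).
#' @param meta Named list of free-form metadata (knee id, trial, marker-set
#'   label, ...).
#' @param check Validate orthonormality of every sample (default `TRUE`).
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(R, rate_hz, seg = c("femur", "tibia"),
                        side = c("R", "L"), mirrored = FALSE,
                        events = NULL, time_s = NULL, meta = list(),
                        check = TRUE) {
  seg <- match.arg(seg)
  side <- match.arg(side)
  if (!is.array(R) || length(dim(R)) != 3L || !all(dim(R)[1:2] == 3L))
    stop_invalid("R must be a 3x3xn array")
  n <- dim(R)[3L]
  if (n < 1L) stop_invalid("pose series must contain at least one sample")
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop_invalid("rate_hz must be positive")
  if (is.null(time_s)) time_s <- (seq_len(n) - 1L) / rate_hz
  if (length(time_s) != n) stop_invalid("time_s must match the sample count")
  if (!is.null(events)) {
    events <- as.integer(events)
    if (any(events < 1L | events > n) || any(diff(events) <= 0L))
      stop_invalid("events must be strictly increasing sample indices in [1, n]")
  }
  if (check) {
    # vectorised orthonormality + determinant check over all samples
    col <- function(j) matrix(R[, j, ], nrow = 3L)
    c1 <- col(1L); c2 <- col(2L); c3 <- col(3L)
    g <- c(colSums(c1^2) - 1, colSums(c2^2) - 1, colSums(c3^2) - 1,
           colSums(c1 * c2), colSums(c1 * c3), colSums(c2 * c3))
    if (max(abs(g)) > 1e-6)
      stop_invalid("pose series contains non-orthonormal orientations")
    d <- R[1, 1, ] * (R[2, 2, ] * R[3, 3, ] - R[2, 3, ] * R[3, 2, ]) -
      R[1, 2, ] * (R[2, 1, ] * R[3, 3, ] - R[2, 3, ] * R[3, 1, ]) +
      R[1, 3, ] * (R[2, 1, ] * R[3, 2, ] - R[2, 2, ] * R[3, 1, ])
    if (max(abs(d - 1)) > 1e-6)
      stop_invalid("pose series contains improper (det != +1) orientations")
  }
  structure(
    list(R = R, rate_hz = rate_hz, time_s = time_s, seg = seg, side = side,
         mirrored = mirrored, events = events, meta = meta),
    class = "pose_series"
  )
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %s, %d samples @ %g Hz, side %s%s\n",
              x$seg, dim(x$R)[3L], x$rate_hz, x$side,
              if (x$mirrored) " (mirrored)" else ""))
  invisible(x)
}

#' @export
mirror_left_to_right.pose_series <- function(x, kind) {
  if (x$side != "L")
    stop_invalid_state("only left-side pose series can be mirrored")
  if (isTRUE(x$mirrored))
    stop_invalid_state("pose series has already been mirrored")
  x$R <- mirror_orientation(x$R)
  x$mirrored <- TRUE
  x
}

#' Joint angle series
#'
#' Ordered Cardan triplets (`alpha_x`, `beta_y`, `gamma_z`, in degrees) for
#' one knee/trial/marker set, over either raw frame indices or a normalized
#' 0–100% gait-cycle domain.
#'
#' @param angles An n x 3 numeric matrix (degrees); columns `alpha_x`
#'   (extension positive), `beta_y` (adduction positive), `gamma_z`
#'   (internal rotation positive).
#' @param domain Numeric vector of length n, strictly increasing: frame
#'   indices or percent of gait cycle.
#' @param domain_type `"frame"` or `"pct"`.
#' @param rate_hz Sampling rate in Hz (required when `domain_type` is
#'   `"frame"`).
#' @param meta Named list of metadata.
#' @return An object of class `joint_angles`.
#' @export
joint_angles <- function(angles, domain = NULL,
                         domain_type = c("frame", "pct"),
                         rate_hz = NULL, meta = list()) {
  domain_type <- match.arg(domain_type)
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L) stop_invalid("angles must have three columns")
  if (nrow(angles) < 2L) stop_invalid("angle series needs at least 2 samples")
  if (!all(is.finite(angles))) stop_invalid("angles must be finite")
  colnames(angles) <- c("alpha_x", "beta_y", "gamma_z")
  n <- nrow(angles)
  if (is.null(domain)) {
    domain <- if (domain_type == "pct") seq(0, 100, length.out = n)
              else seq_len(n)
  }
  if (length(domain) != n || any(diff(domain) <= 0))
    stop_invalid("domain must be strictly increasing and match the sample count")
  if (domain_type == "pct" &&
      (domain[1L] < -1e-9 || domain[n] > 100 + 1e-9))
    stop_invalid("pct domain must lie within [0, 100]")
  structure(
    list(angles = angles, domain = as.numeric(domain),
         domain_type = domain_type, rate_hz = rate_hz, meta = meta),
    class = "joint_angles"
  )
}

#' @export
print.joint_angles <- function(x, ...) {
  cat(sprintf("<joint_angles> %d samples over %s domain\n",
              nrow(x$angles), x$domain_type))
  rng <- apply(x$angles, 2, range)
  cat(sprintf("  alpha_x [%.1f, %.1f]  beta_y [%.1f, %.1f]  gamma_z [%.1f, %.1f] deg\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' @export
as.data.frame.joint_angles <- function(x, ...) {
  data.frame(domain = x$domain,
             alpha_x = x$angles[, 1L],
             beta_y = x$angles[, 2L],
             gamma_z = x$angles[, 3L])
}

# Joint rotation entries T = femur^T tibia for pose arrays, as a list of the
# nine entry vectors (length n each).  Vectorised over samples.
joint_entries <- function(F, B) {
  ent <- vector("list", 9L)
  k <- 1L
  for (j in 1:3) for (l in 1:3) {
    ent[[k]] <- F[1, j, ] * B[1, l, ] + F[2, j, ] * B[2, l, ] +
      F[3, j, ] * B[3, l, ]
    k <- k + 1L
  }
  names(ent) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                  "r31", "r32", "r33")
  ent
}

# Cardan extraction for a 3x3xn array of joint rotations, with per-channel
# unwrapping.  Returns an n x 3 matrix in degrees.
extract_cardan_series <- function(T, unwrap = TRUE, gimbal_tol = 1e-7) {
  ang <- cardan_from_entries(T[1, 1, ], T[1, 2, ], T[1, 3, ],
                             T[2, 1, ], T[2, 2, ], T[2, 3, ], T[3, 3, ],
                             gimbal_tol = gimbal_tol)
  if (unwrap && nrow(ang) > 1L) {
    ang[, 1L] <- unwrap_deg(ang[, 1L])
    ang[, 3L] <- unwrap_deg(ang[, 3L])
  }
  ang
}

# Rebuild a 3x3xn rotation array from an n x 3 matrix of Cardan angles
# (degrees); exact inverse of extract_cardan_series up to unwrapping.
cardan_series_to_array <- function(angles) {
  a <- deg2rad(angles[, 1L]); b <- deg2rad(angles[, 2L]); g <- deg2rad(angles[, 3L])
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cg <- cos(g); sg <- sin(g)
  n <- length(a)
  T <- array(0, c(3L, 3L, n))
  T[1, 1, ] <- cb * cg
  T[1, 2, ] <- -cb * sg
  T[1, 3, ] <- sb
  T[2, 1, ] <- ca * sg + sa * sb * cg
  T[2, 2, ] <- ca * cg - sa * sb * sg
  T[2, 3, ] <- -sa * cb
  T[3, 1, ] <- sa * sg - ca * sb * cg
  T[3, 2, ] <- sa * cg + ca * sb * sg
  T[3, 3, ] <- ca * cb
  T
}

#' Compute tibio-femoral joint angles from segment pose series
#'
#' Per sample, extracts the intrinsic XYZ Cardan angles of the joint
#' rotation \eqn{R_{fem}^T R_{tib}}.  The `alpha_x` and `gamma_z` channels
#' are unwrapped across the +/-180 degree boundary.  Left-side series must
#' be mirrored first ([mirror_left_to_right()]).
#'
#' @param femur,tibia [pose_series()] objects (or plain 3x3xn arrays),
#'   time-aligned and of equal length.
#' @return A [joint_angles()] series over the raw frame domain.
#' @export
compute_joint_angles <- function(femur, tibia) {
  fa <- if (inherits(femur, "pose_series")) femur$R else femur
  ta <- if (inherits(tibia, "pose_series")) tibia$R else tibia
  if (!is.array(fa) || !is.array(ta) || length(dim(fa)) != 3L ||
      length(dim(ta)) != 3L)
    stop_invalid("femur and tibia must be pose series or 3x3xn arrays")
  if (dim(fa)[3L] != dim(ta)[3L])
    stop_invalid("femur and tibia series must have equal length")
  if (inherits(femur, "pose_series") && inherits(tibia, "pose_series")) {
    if (femur$side != tibia$side || !identical(femur$mirrored, tibia$mirrored))
      stop_invalid("femur and tibia series disagree on side/mirroring")
    if (femur$side == "L" && !isTRUE(femur$mirrored))
      stop_invalid("left-side series must be mirrored before angle extraction")
  }
  ent <- joint_entries(fa, ta)
  ang <- cardan_from_entries(ent$r11, ent$r12, ent$r13,
                             ent$r21, ent$r22, ent$r23, ent$r33)
  if (nrow(ang) > 1L) {
    ang[, 1L] <- unwrap_deg(ang[, 1L])
    ang[, 3L] <- unwrap_deg(ang[, 3L])
  }
  rate <- if (inherits(femur, "pose_series")) femur$rate_hz else NULL
  meta <- if (inherits(femur, "pose_series")) femur$meta else list()
  joint_angles(ang, domain_type = "frame", rate_hz = rate, meta = meta)
}

#' Clinical display convention for joint angles
#'
#' For presentation, flexion is shown positive although it is a negative
#' rotation about the laterally pointing x-axis.  Only the displayed sign
#' flips; stored data are unchanged.
#'
#' @param x A [joint_angles()] series.
#' @return A data frame with columns `domain`, `flex_deg` (positive
#'   flexion), `add_deg` and `introt_deg`.
#' @export
to_clinical_display <- function(x) {
  if (!inherits(x, "joint_angles")) stop_invalid("x must be a joint_angles series")
  data.frame(domain = x$domain,
             flex_deg = -x$angles[, 1L],
             add_deg = x$angles[, 2L],
             introt_deg = x$angles[, 3L])
}

#' Time-normalize joint angles to the gait cycle
#'
#' Resamples each gait cycle (delimited by consecutive event indices) onto
#' `n_norm` evenly spaced points spanning 0–100% of the cycle by linear
#' interpolation.
#'
#' @param x A [joint_angles()] series over the frame domain.
#' @param events Integer sample indices of cycle boundaries, strictly
#'   increasing, at least two.
#' @param n_norm Number of output samples per cycle (default 101,
#'   0–100% inclusive).
#' @return A list of [joint_angles()] series, one per cycle, over the
#'   percent-cycle domain.
#' @export
normalize_gait_cycle <- function(x, events, n_norm = 101L) {
  if (!inherits(x, "joint_angles")) stop_invalid("x must be a joint_angles series")
  if (x$domain_type != "frame")
    stop_invalid("series is already cycle-normalized")
  events <- as.integer(events)
  n <- nrow(x$angles)
  if (length(events) < 2L)
    stop_invalid("at least two event indices are required")
  if (any(events < 1L | events > n) || any(diff(events) <= 0L))
    stop_invalid("events must be strictly increasing sample indices in [1, n]")
  pct <- seq(0, 100, length.out = n_norm)
  lapply(seq_len(length(events) - 1L), function(i) {
    idx <- events[i]:events[i + 1L]
    xin <- x$domain[idx]
    xout <- seq(xin[1L], xin[length(xin)], length.out = n_norm)
    ang <- vapply(1:3, function(ch)
      stats::approx(xin, x$angles[idx, ch], xout = xout)$y,
      numeric(n_norm))
    meta <- x$meta
    meta$cycle <- i
    joint_angles(ang, domain = pct, domain_type = "pct",
                 rate_hz = x$rate_hz, meta = meta)
  })
}
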