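# Rotation and frame-construction primitives.
#
# Conventions used throughout the package:
#   * positions in mm, angles in degrees (radians only inside formulas),
#   * segment frames are right-handed orthonormal 3x3 matrices whose
#     columns are (X anterior-ish, Y along the segment long axis pointing
#     proximally, Z lateral-ish),
#   * per-frame quantities are vectorized: rotation stacks are arrays of
#     dim c(n, 3, 3), point stacks are matrices n x 3.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, taking the angle in
#' degrees.
#'
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(deg) {
  a <- deg * DEG2RAD
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(deg) {
  a <- deg * DEG2RAD
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(deg) {
  a <- deg * DEG2RAD
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

# Row-wise cross product of n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(a) sqrt(rowSums(a * a))

unit_rows <- function(a) a / row_norms(a)

#' Build right-handed frames from a long axis and a lateral reference
#'
#' Given per-frame long-axis vectors (to become column Y) and a reference
#' vector fixing the remaining degree of freedom, returns the stack of
#' orthonormal frames. With `ref_axis = "z"` the reference approximates the
#' lateral (Z) direction and X = unit(Y x ref), Z = X x Y; with
#' `ref_axis = "x"` the reference approximates the anterior (X) direction
#' and Z = unit(ref x Y), X = Y x Z. Either way the frame is exactly
#' orthonormal with determinant +1.
#'
#' @param y_vec n x 3 matrix of long-axis vectors (not necessarily unit).
#' @param ref n x 3 matrix of reference vectors.
#' @param ref_axis `"z"` or `"x"`, which axis `ref` approximates.
#' @param tol relative collinearity tolerance.
#' @param what label used in degenerate-geometry error messages.
#' @return array of dim c(n, 3, 3); `[i, , ]` is the i-th frame.
#' @keywords internal
frames_from_axes <- function(y_vec, ref, ref_axis = c("z", "x"),
                             tol = 1e-8, what = "segment") {
  ref_axis <- match.arg(ref_axis)
  n <- nrow(y_vec)
  ny <- row_norms(y_vec)
  if (any(ny < tol)) {
    stop(sprintf("degenerate geometry for %s: zero-length long axis at frame %d",
                 what, which(ny < tol)[1]))
  }
  y <- y_vec / ny
  if (ref_axis == "z") {
    x0 <- cross_rows(y, ref)
  } else {
    x0 <- NULL
  }
  if (ref_axis == "z") {
    nx <- row_norms(x0)
    bad <- nx < tol * row_norms(ref)
    if (any(bad)) {
      stop(sprintf("degenerate geometry for %s: collinear markers at frame %d",
                   what, which(bad)[1]))
    }
    x <- x0 / nx
    z <- cross_rows(x, y)
    out <- array(0, c(n, 3, 3))
    out[, , 1] <- x
    out[, , 2] <- y
    out[, , 3] <- z
  } else {
    z0 <- cross_rows(ref, y)
    nz <- row_norms(z0)
    bad <- nz < tol * row_norms(ref)
    if (any(bad)) {
      stop(sprintf("degenerate geometry for %s: collinear markers at frame %d",
                   what, which(bad)[1]))
    }
    z <- z0 / nz
    x <- cross_rows(y, z)
    out <- array(0, c(n, 3, 3))
    out[, , 1] <- x
    out[, , 2] <- y
    out[, , 3] <- z
  }
  out
}

# Relative rotation stacks: R_rel[i] = t(Ra[i]) %*% Rb[i], vectorized.
relative_rotation <- function(ra, rb) {
  n <- dim(ra)[1]
  out <- array(0, c(n, 3, 3))
  for (j in 1:3) {
    for (k in 1:3) {
      out[, j, k] <- ra[, 1, j] * rb[, 1, k] +
        ra[, 2, j] * rb[, 2, k] +
        ra[, 3, j] * rb[, 3, k]
    }
  }
  out
}

#' Euler decompositions of rotation stacks
#'
#' `euler_yxy()` decomposes R = Ry(a) Rx(b) Ry(c) (the shoulder
#' mobile-axis sequence: plane of elevation, elevation, axial rotation).
#' `euler_zxy()` decomposes R = Rz(a) Rx(b) Ry(c) (elbow/wrist sequence:
#' flexion, deviation/carrying angle, axial rotation). Angles are returned
#' in degrees, columns `a`, `b`, `c`. Near-gimbal frames (middle angle
#' within ~1e-3 deg of its singular values) are resolved by carrying the
#' previous frame's first angle and flagged via the `gimbal` attribute.
#'
#' @param r array dim c(n, 3, 3).
#' @return n x 3 matrix with attribute `gimbal` (logical n-vector).
#' @keywords internal
#' @name euler-decompositions
NULL

#' @rdname euler-decompositions
euler_yxy <- function(r) {
  n <- dim(r)[1]
  cb <- pmin(1, pmax(-1, r[, 2, 2]))
  b <- acos(cb) * RAD2DEG
  a <- atan2(r[, 1, 2], r[, 3, 2]) * RAD2DEG
  cc <- atan2(r[, 2, 1], -r[, 2, 3]) * RAD2DEG
  gimbal <- pmin(b, 180 - b) < 1e-3
  if (any(gimbal)) {
    # plane of elevation undefined; total rotation about Y is a + c
    total <- atan2(r[, 1, 3] - r[, 3, 1], r[, 1, 1] + r[, 3, 3]) * RAD2DEG
    for (i in which(gimbal)) {
      prev <- if (i > 1) a[i - 1] else 0
      a[i] <- prev
      cc[i] <- total[i] - prev * sign(cos(b[i] * DEG2RAD))
    }
  }
  out <- cbind(a = a, b = b, c = cc)
  attr(out, "gimbal") <- gimbal
  out
}

#' @rdname euler-decompositions
euler_zxy <- function(r) {
  sb <- pmin(1, pmax(-1, r[, 3, 2]))
  b <- asin(sb) * RAD2DEG
  a <- atan2(-r[, 1, 2], r[, 2, 2]) * RAD2DEG
  cc <- atan2(-r[, 3, 1], r[, 3, 3]) * RAD2DEG
  gimbal <- (90 - abs(b)) < 1e-3
  if (any(gimbal)) {
    total <- atan2(r[, 2, 1], r[, 1, 1]) * RAD2DEG
    for (i in which(gimbal)) {
      prev <- if (i > 1) a[i - 1] else 0
      a[i] <- prev
      cc[i] <- total[i] - prev
    }
  }
  out <- cbind(a = a, b = b, c = cc)
  attr(out, "gimbal") <- gimbal
  out
}

#' Unwrap an angle series in degrees
#'
#' Removes jumps larger than 180 degrees between adjacent samples so the
#' series is continuous.
#'
#' @param x numeric vector of angles (deg).
#' @return unwrapped vector.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jumps <- round(d / 360)
  x - c(0, cumsum(jumps)) * 360
}
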