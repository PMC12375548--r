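#' Rigid transform
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix,
#' determinant +1) together with a translation in mm.  Transforms map points
#' expressed in a local frame into the parent frame:
#' `x_parent = R x_local + t`.
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!identical(dim(rotation), c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (length(translation) != 3L)
    stop("translation must have length 3")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6 || det(rotation) < 0)
    stop("rotation is not a proper orthonormal matrix (max deviation ",
         format(err), ")")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` maps local coordinates through `b` then `a`, i.e. the
#' result equals the product of the corresponding homogeneous matrices.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse transform.
#' @export
rt_inverse <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$rotation), -as.numeric(t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to points
#' @param x A `rigid_transform`.
#' @param points A length-3 vector or 3 x n matrix of points (mm).
#' @return Transformed points in the same shape.
#' @export
rt_apply <- function(x, points) {
  stopifnot(inherits(x, "rigid_transform"))
  if (is.matrix(points)) {
    x$rotation %*% points + x$translation
  } else {
    as.numeric(x$rotation %*% points) + x$translation
  }
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  translation (mm):", format(x$translation), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Elementary rotation matrices
#' @param angle rotation angle in rad.
#' @return 3x3 rotation matrix.
#' @rdname elementary-rotations
#' @export
rot_x <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Body-fixed X-Y-Z Euler angles to rotation matrix
#'
#' The package's convention for all frame-orientation offsets:
#' `R = Rx(a) Ry(b) Rz(c)` with angles in rad.
#'
#' @param angles length-3 numeric, rad.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(angles) {
  stopifnot(length(angles) == 3L)
  rot_x(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
}

#' Rotation matrix to body-fixed X-Y-Z Euler angles
#' @param R 3x3 rotation matrix.
#' @return length-3 numeric angles in rad, each in (-pi, pi].
#' @export
rotation_to_euler <- function(R) {
  # R = Rx(a) Ry(b) Rz(c); R[1,3] = sin(b)
  b <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
  } else {
    a <- atan2(R[2, 1], R[2, 2])  # gimbal lock: fold c into a
    c <- 0
  }
  c(a, b, c)
}

#' Unit quaternion (scalar-first) to rotation matrix
#'
#' Quaternions are scalar-first `(w, x, y, z)`, right-handed, and are
#' normalized before conversion.
#'
#' @param q length-4 numeric quaternion.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  stopifnot(length(q) == 4L)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero-norm quaternion")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Rotation matrix to unit quaternion (scalar-first)
#' @param R 3x3 rotation matrix.
#' @return length-4 quaternion `(w, x, y, z)` with non-negative scalar part.
#' @export
rotation_to_quat <- function(R) {
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
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Wrap angles to (-pi, pi]
#' @param x numeric vector of angles in rad.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
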