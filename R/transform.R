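#' Rigid transform between two coordinate frames
#'
#' A rigid transform maps source-frame coordinates into target-frame
#' coordinates with column-vector convention `p' = R %*% p + t`. The rotation
#' must be orthonormal with determinant +1 (no scale, no reflection).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, millimetres.
#' @param tol tolerance for the orthonormality and determinant checks.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' T1 <- rigid_transform(rotation_axis_angle(c(0, 0, 1), pi / 6), c(10, 0, 0))
#' rt_compose(rt_inverse(T1), T1)  # identity
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    abort_parameter("rotation must be a finite 3x3 matrix")
  if (length(translation) != 3L || !all(is.finite(translation)))
    abort_parameter("translation must be a finite length-3 vector")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    abort_parameter("rotation is not orthonormal within tolerance")
  if (abs(det(rotation) - 1) > tol)
    abort_parameter("rotation determinant is not +1 (reflection or scale)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return A `rigid_transform` with identity rotation and zero translation.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; the axis is normalized internally.
#'
#' @param axis length-3 rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) abort_parameter("rotation axis must be non-zero")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform` (target-to-source map).
#' @export
rt_inverse <- function(transform) {
  R <- transform$rotation
  rigid_transform(t(R), -as.numeric(t(R) %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `second` first and `first` afterwards,
#' i.e. `first o second` in function-composition order.
#'
#' @param first,second `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(first, second) {
  rigid_transform(first$rotation %*% second$rotation,
                  as.numeric(first$rotation %*% second$translation) +
                    first$translation)
}

#' Rotation angle of a rigid transform
#' @param transform a `rigid_transform`.
#' @return Rotation angle in radians, in `[0, pi]`.
#' @export
rt_angle <- function(transform) {
  acos(max(-1, min(1, (sum(diag(transform$rotation)) - 1) / 2)))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rt_angle(x) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# points: N x 3 matrix -> transformed N x 3 matrix
transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}
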