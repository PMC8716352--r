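#' Rigid transforms (rotation + translation)
#'
#' A `rigid_transform` maps points `p` to `rotation %*% p + translation`.
#' It is the currency of robot-to-image calibration: the calibration
#' pipeline estimates the transform linking the imaging world frame to
#' the robot/tool frame. The rotation must be orthonormal with
#' determinant +1 (within 1e-9); composition and inversion stay closed
#' under these invariants.
#'
#' @param rotation 3x3 orthonormal matrix, det = +1.
#' @param translation numeric length-3, mm.
#' @return An object of class `rigid_transform` with fields `rotation`
#'   and `translation`.
#' @examples
#' t1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(5, -3, 12))
#' p <- c(10, 0, 0)
#' rt_apply(rt_inverse(t1), rt_apply(t1, p))  # recovers p
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as_point3(translation, "translation")
  cbct_check(all(dim(rotation) == c(3, 3)), "cbctnav_validation",
             "rotation must be a 3x3 matrix")
  cbct_check(max(abs(crossprod(rotation) - diag(3))) < 1e-9,
             "cbctnav_validation", "rotation must be orthonormal within 1e-9")
  cbct_check(abs(det(rotation) - 1) < 1e-9, "cbctnav_validation",
             "rotation must be proper (det = +1); reflections are not rigid")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points a length-3 vector or an n x 3 matrix (rows = points, mm).
#' @return Transformed points in the same shape as the input.
#' @export
rt_apply <- function(transform, points) {
  cbct_check(is_rigid_transform(transform), "cbctnav_validation",
             "transform must be a rigid_transform")
  if (is.null(dim(points))) {
    as.vector(transform$rotation %*% as_point3(points) + transform$translation)
  } else {
    pts <- as_points_matrix(points)
    sweep(pts %*% t(transform$rotation), 2, transform$translation, `+`)
  }
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`,
#' i.e. `rt_apply(rt_compose(second, first), p) == rt_apply(second, rt_apply(first, p))`.
#'
#' @param second,first [rigid_transform()] objects.
#' @export
rt_compose <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.vector(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @export
rt_inverse <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; used to build test poses and to construct
#' trajectory directions at prescribed angulations.
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle, degrees, right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as_point3(axis, "axis")
  n <- sqrt(sum(u^2))
  cbct_check(n > 0, "cbctnav_validation", "axis must be nonzero")
  u <- u / n
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Angle between two rotations
#'
#' The geodesic distance on SO(3): the magnitude of the single rotation
#' taking one orientation to the other. Used to score calibration
#' round-trip accuracy.
#'
#' @param r1,r2 3x3 rotation matrices.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_between <- function(r1, r2) {
  tr <- sum(diag(t(r1) %*% r2))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Least-squares rigid fit between paired point sets
#'
#' Closed-form (SVD-based) solution of the orthogonal Procrustes
#' problem restricted to proper rotations: finds the rigid transform
#' `T` minimising `sum ||T(source_i) - target_i||^2`. A reflection in
#' the unconstrained optimum is corrected so the returned rotation has
#' determinant +1. This is the estimator behind robot-to-image
#' calibration once fiducial correspondence is known.
#'
#' @param source_points,target_points n x 3 matrices (or lists of
#'   3-vectors), n >= 3, paired row-by-row, mm.
#' @return A [rigid_transform()] mapping source to target.
#' @section Errors: signals a `cbctnav_degenerate_geometry` condition
#'   when the source points are collinear (rotation not identifiable).
#' @export
fit_rigid_transform <- function(source_points, target_points) {
  src <- as_points_matrix(source_points, "source_points")
  tgt <- as_points_matrix(target_points, "target_points")
  cbct_check(nrow(src) == nrow(tgt), "cbctnav_validation",
             "source and target must have the same number of points")
  cbct_check(nrow(src) >= 3, "cbctnav_validation",
             "need at least 3 paired points for a rigid fit")
  cs <- colMeans(src); ct <- colMeans(tgt)
  sc <- sweep(src, 2, cs); tc <- sweep(tgt, 2, ct)
  sv <- svd(sc)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1))
    cbct_abort("cbctnav_degenerate_geometry",
               "source points are collinear; rotation is not identifiable")
  h <- crossprod(sc, tc)              # 3x3 cross-covariance
  dec <- svd(h)
  s <- sign(det(dec$v %*% t(dec$u)))
  rot <- dec$v %*% diag(c(1, 1, s)) %*% t(dec$u)
  rigid_transform(rot, ct - as.vector(rot %*% cs))
}

#' Fiducial registration error (FRE)
#'
#' Root-mean-square residual of a fitted transform at the fiducials:
#' `sqrt(mean ||T(source_i) - target_i||^2)`. The standard summary of
#' point-based registration quality.
#'
#' @param transform a [rigid_transform()].
#' @param source_points,target_points paired n x 3 point sets, mm.
#' @return RMS residual in mm.
#' @export
fiducial_registration_error <- function(transform, source_points, target_points) {
  src <- as_points_matrix(source_points, "source_points")
  tgt <- as_points_matrix(target_points, "target_points")
  cbct_check(nrow(src) == nrow(tgt), "cbctnav_validation",
             "source and target must have the same number of points")
  res <- rt_apply(transform, src) - tgt
  sqrt(mean(rowSums(res^2)))
}
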