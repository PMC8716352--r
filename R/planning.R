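# Trajectory planning under gantry angulation limits. Conventions
# (LPS world frame, DICOM): craniocaudal angulation is the tilt of
# the needle direction toward the head (+, cranial = +S) or feet
# (-, caudal); RAO/LAO is the tilt in the axial plane, signed + = RAO
# (toward the patient's right = -L). The system's reachable envelope
# is 17.5 deg cranial, 32.5 deg caudal and +/-20 deg RAO/LAO.

#' Default angulation limits of the robotic assistance system
#'
#' @return `list(cranial_deg = 17.5, caudal_deg = 32.5, raolao_deg = 20)`.
#' @export
angulation_limits <- function() {
  list(cranial_deg = 17.5, caudal_deg = 32.5, raolao_deg = 20)
}

#' Decompose a needle direction into angulation angles
#'
#' `craniocaudal_deg` is the arcsine of the superior component
#' (signed, + toward cranial); `raolao_deg` is the angle of the axial
#' projection away from the anterior-posterior axis, signed + = RAO.
#' A purely craniocaudal direction has an undefined RAO/LAO angle and
#' returns 0 by convention.
#'
#' @param direction_u unit 3-vector, LPS.
#' @return `c(craniocaudal_deg, raolao_deg)`.
#' @export
angulation_angles <- function(direction_u) {
  u <- as_point3(direction_u, "direction_u")
  cbct_check(abs(sqrt(sum(u^2)) - 1) < 1e-6, "cbctnav_validation",
             "direction_u must be a unit vector")
  cc <- asin(pmin(1, pmax(-1, u[3]))) * 180 / pi
  rl <- atan2(-u[1], abs(u[2])) * 180 / pi   # + = RAO = patient right = -L
  c(craniocaudal_deg = cc, raolao_deg = rl)
}

#' Construct a unit direction at prescribed angulation angles
#'
#' Inverse of [angulation_angles()] on the reachable grid: builds the
#' LPS direction with the given craniocaudal and RAO/LAO angles,
#' relative to a posterior-going (anterior entry) base direction.
#'
#' @param craniocaudal_deg signed degrees, + cranial.
#' @param raolao_deg signed degrees, + RAO.
#' @return Unit 3-vector (LPS).
#' @export
trajectory_direction <- function(craniocaudal_deg, raolao_deg) {
  cc <- craniocaudal_deg * pi / 180
  rl <- raolao_deg * pi / 180
  c(-cos(cc) * sin(rl), cos(cc) * cos(rl), sin(cc))
}

#' Plan a needle trajectory from entry and target points
#'
#' Turns the interventionist's chosen entry point A and target point B
#' into a validated plan: direction, depth, angulation decomposition,
#' in-plane/out-of-plane classification and reachability under the
#' system's angulation limits.
#'
#' @param entry_A,target_B points, image world mm.
#' @param limits angulation limits, see [angulation_limits()].
#' @param plane_tol_deg classification tolerance: the plan is
#'   `in_plane` iff `|craniocaudal_deg| < plane_tol_deg` (default 1;
#'   a physical setup cannot hit exactly 0).
#' @return A `trajectory_plan`: `entry_A`, `target_B`, `direction_u`,
#'   `depth_mm`, `craniocaudal_deg`, `raolao_deg`, `plane_class`,
#'   `reachable`.
#' @section Errors: `cbctnav_zero_length` when A equals B.
#' @examples
#' plan_trajectory(c(0, 0, 0), c(0, 100, 0))  # pure AP, in-plane
#' @export
plan_trajectory <- function(entry_A, target_B, limits = angulation_limits(),
                            plane_tol_deg = 1) {
  a <- as_point3(entry_A, "entry_A")
  b <- as_point3(target_B, "target_B")
  d <- b - a
  depth <- sqrt(sum(d^2))
  if (depth <= 0)
    cbct_abort("cbctnav_zero_length", "entry and target coincide: zero-length trajectory")
  u <- d / depth
  ang <- angulation_angles(u)
  eps <- 1e-9  # inclusive limits, robust to angle-decomposition rounding
  reachable <- ang[["craniocaudal_deg"]] <= limits$cranial_deg + eps &&
    ang[["craniocaudal_deg"]] >= -limits$caudal_deg - eps &&
    abs(ang[["raolao_deg"]]) <= limits$raolao_deg + eps
  structure(list(entry_A = a, target_B = b, direction_u = u, depth_mm = depth,
                 craniocaudal_deg = ang[["craniocaudal_deg"]],
                 raolao_deg = ang[["raolao_deg"]],
                 plane_class = if (abs(ang[["craniocaudal_deg"]]) < plane_tol_deg)
                   "in_plane" else "out_of_plane",
                 reachable = reachable, limits = limits),
            class = "trajectory_plan")
}

#' @export
print.trajectory_plan <- function(x, ...) {
  cat(sprintf("trajectory_plan: depth %.1f mm, craniocaudal %+.2f deg, RAO/LAO %+.2f deg\n",
              x$depth_mm, x$craniocaudal_deg, x$raolao_deg))
  cat(sprintf("  %s, %s\n", x$plane_class,
              if (x$reachable) "reachable" else "NOT reachable under angulation limits"))
  invisible(x)
}

#' Map a plan into the robot frame as a guide pose
#'
#' Applies the calibration transform (image world -> robot/tool frame)
#' to the plan and backs the needle-guide position off the entry point
#' along the needle axis by `standoff_mm` so the guide clears the skin.
#'
#' @param plan a [plan_trajectory()] result.
#' @param calibration_transform [rigid_transform()] image -> robot
#'   frame (e.g. `calibrate(...)$transform`).
#' @param standoff_mm guide standoff along the negative needle axis,
#'   mm (default 20).
#' @param force bypass the reachability refusal (default FALSE).
#' @return `list(position, axis, standoff_mm)` in the robot frame.
#' @section Errors: `cbctnav_unreachable` for a non-reachable plan
#'   unless `force = TRUE`.
#' @export
image_to_robot <- function(plan, calibration_transform, standoff_mm = 20,
                           force = FALSE) {
  cbct_check(inherits(plan, "trajectory_plan"), "cbctnav_validation",
             "plan must be a trajectory_plan")
  cbct_check(is_rigid_transform(calibration_transform), "cbctnav_validation",
             "calibration_transform must be a rigid_transform")
  if (!plan$reachable && !force)
    cbct_abort("cbctnav_unreachable",
               "plan violates the angulation limits; pass force = TRUE to override")
  entry_r <- rt_apply(calibration_transform, plan$entry_A)
  axis <- as.vector(calibration_transform$rotation %*% plan$direction_u)
  list(position = entry_r - standoff_mm * axis, axis = axis,
       standoff_mm = standoff_mm)
}
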