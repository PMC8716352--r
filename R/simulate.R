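# Monte-Carlo stand-in for the physical needle-placement experiment.
# The deterministic part of a robot-guided insertion is the guide
# axis; what remains stochastic is (a) a small angular error of the
# actual needle path about the planned axis and (b) the manual
# insertion depth. Both are modelled as independent Gaussians, plus a
# truncated-Gaussian procedural time.

#' Noise parameters for simulated needle insertions
#'
#' Defaults are set to the study-scale dispersion of a robot-assisted
#' phantom experiment: transverse angular error SD 0.68 deg and
#' insertion-depth SD 1.55 mm (the reported angular/longitudinal
#' deviation STDs), with procedural time 361 +/- 43 s.
#'
#' @param angular_sd_deg SD of each of the two transverse angular
#'   error components, degrees.
#' @param depth_sd_mm SD of the manual insertion-depth error, mm.
#' @param time_mean_s,time_sd_s procedural-time distribution, s
#'   (truncated at > 0).
#' @return A `needle_noise` list.
#' @export
needle_noise <- function(angular_sd_deg = 0.68, depth_sd_mm = 1.55,
                         time_mean_s = 361, time_sd_s = 43) {
  cbct_check(all(c(angular_sd_deg, depth_sd_mm, time_sd_s) >= 0) &&
               time_mean_s >= 0, "cbctnav_validation",
             "noise parameters must all be >= 0")
  structure(list(angular_sd_deg = angular_sd_deg, depth_sd_mm = depth_sd_mm,
                 time_mean_s = time_mean_s, time_sd_s = time_sd_s),
            class = "needle_noise")
}

#' Per-group noise defaults for the simulated study
#'
#' In-plane and out-of-plane insertions share the angular and depth
#' dispersion but differ in procedural time (337 +/- 50 s vs
#' 380 +/- 26 s), reflecting the extra gantry handling of out-of-plane
#' paths.
#'
#' @return `list(in_plane = <needle_noise>, out_of_plane = <needle_noise>)`.
#' @export
default_study_noise <- function() {
  list(in_plane = needle_noise(time_mean_s = 337, time_sd_s = 50),
       out_of_plane = needle_noise(time_mean_s = 380, time_sd_s = 26))
}

# orthonormal basis perpendicular to unit vector u
transverse_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Simulate one needle insertion
#'
#' Draws the actual needle tip C for a planned trajectory: the planned
#' unit direction is rotated by a small random rotation whose two
#' transverse angular components are independent `N(0, angular_sd)`,
#' and the insertion depth is `|AB| + N(0, depth_sd)` (the depth is
#' controlled manually, not by the robot). The realised entry point is
#' taken identical to the planned one, which is the experimental
#' observation at 0.48 mm control-scan resolution.
#'
#' @param plan a [plan_trajectory()] result.
#' @param noise a [needle_noise()].
#' @param seed integer RNG seed (required; outcomes are reproducible).
#' @param group_label `"in_plane"` or `"out_of_plane"`; default taken
#'   from the plan's classification.
#' @return A `needle_outcome`: `entry_A`, `target_B`, `tip_C`,
#'   `procedural_time_s`, `group_label`, `iterations` (needle
#'   repositioning count; 0 — the robot-guided procedure needed none),
#'   plus the realised `direction_actual`.
#' @section Errors: `cbctnav_zero_length` on a degenerate plan.
#' @export
simulate_needle_outcome <- function(plan, noise = needle_noise(), seed,
                                    group_label = NULL) {
  cbct_check(inherits(plan, "trajectory_plan"), "cbctnav_validation",
             "plan must be a trajectory_plan")
  cbct_check(inherits(noise, "needle_noise"), "cbctnav_validation",
             "noise must be a needle_noise")
  if (plan$depth_mm <= 0)
    cbct_abort("cbctnav_zero_length", "zero-length trajectory")
  set.seed(as.integer(seed))

  u <- plan$direction_u
  th <- rnorm(2, 0, noise$angular_sd_deg * pi / 180)  # transverse components, rad
  theta <- sqrt(sum(th^2))
  v <- if (theta == 0) u else {
    b <- transverse_basis(u)
    t_hat <- (th[1] * b$e1 + th[2] * b$e2) / theta
    cos(theta) * u + sin(theta) * t_hat        # exact rotation by theta
  }
  d <- plan$depth_mm + rnorm(1, 0, noise$depth_sd_mm)
  tip <- plan$entry_A + d * v

  time_s <- noise$time_mean_s
  if (noise$time_sd_s > 0) {
    repeat {
      time_s <- rnorm(1, noise$time_mean_s, noise$time_sd_s)
      if (time_s > 0) break
    }
  }

  structure(list(entry_A = plan$entry_A, target_B = plan$target_B,
                 tip_C = tip, procedural_time_s = time_s,
                 group_label = group_label %||% plan$plane_class,
                 iterations = 0L, direction_actual = v,
                 depth_actual_mm = d),
            class = "needle_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the full phantom study
#'
#' Reproduces the study design: each of the eight lesions is targeted
#' twice, once with an in-plane trajectory (craniocaudal angulation 0,
#' RAO/LAO only) and once out-of-plane (additional craniocaudal tilt),
#' for 16 trajectories total. Angles are drawn inside the reachable
#' envelope (out-of-plane craniocaudal tilt at least 3 deg so the two
#' groups are cleanly separated); entry points are placed at a
#' clinically plausible depth of 80-120 mm from the lesion. Every plan
#' is checked for reachability.
#'
#' @param tool_model a [make_tool_model()] result (carried into the
#'   outcome metadata; the study itself is geometric).
#' @param lesions list of 8 `list(center, radius)` lesions
#'   (default [default_lesions()]).
#' @param limits angulation limits, see [angulation_limits()].
#' @param noise_by_group per-group [needle_noise()], see
#'   [default_study_noise()].
#' @param seed integer RNG seed; the whole study is reproducible.
#' @return List of 16 `needle_outcome`s (8 in-plane, 8 out-of-plane),
#'   each carrying its `plan` and `lesion_radius`.
#' @section Errors: signals `cbctnav_unreachable` if a drawn plan
#'   fails the reachability check (cannot happen with the default
#'   sampling envelope, which is strictly inside the limits).
#' @export
simulate_study <- function(tool_model = make_tool_model(),
                           lesions = default_lesions(),
                           limits = angulation_limits(),
                           noise_by_group = default_study_noise(),
                           seed = 1L) {
  cbct_check(length(lesions) == 8, "cbctnav_validation",
             "the study design uses exactly 8 lesions")
  set.seed(as.integer(seed))
  # pre-draw all geometry/outcome seeds so per-outcome seeding stays
  # reproducible regardless of evaluation order
  sub_seeds <- sample.int(2^30, 16)

  outcomes <- vector("list", 16)
  k <- 0
  for (i in seq_along(lesions)) {
    for (grp in c("in_plane", "out_of_plane")) {
      k <- k + 1
      cc <- if (grp == "in_plane") 0 else {
        # nonzero craniocaudal tilt, clearly out of plane, inside limits
        s <- runif(1, -1, 1)
        if (s >= 0) 3 + s * (limits$cranial_deg - 1 - 3)
        else -3 + s * (limits$caudal_deg - 1 - 3)
      }
      rl <- runif(1, -(limits$raolao_deg - 1), limits$raolao_deg - 1)
      depth <- runif(1, 80, 120)
      target <- as_point3(lesions[[i]]$center)
      entry <- target - depth * trajectory_direction(cc, rl)
      plan <- plan_trajectory(entry, target, limits = limits)
      if (!plan$reachable)
        cbct_abort("cbctnav_unreachable", sprintf(
          "lesion %d admits no reachable %s trajectory under the angulation limits", i, grp))
      out <- simulate_needle_outcome(plan, noise = noise_by_group[[grp]],
                                     seed = sub_seeds[k], group_label = grp)
      out$plan <- plan
      out$lesion_radius <- lesions[[i]]$radius
      out$lesion_index <- i
      outcomes[[k]] <- out
    }
  }
  outcomes
}
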