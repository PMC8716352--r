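# Shared generators for property-style tests. All randomness is
# locally seeded so every test is reproducible in isolation.

random_rigid <- function(max_angle_deg = 180, max_trans_mm = 50) {
  ax <- rnorm(3)
  tr <- rnorm(3)
  tr <- tr / sqrt(sum(tr^2)) * runif(1, 0, max_trans_mm)
  rigid_transform(rotation_about_axis(ax, runif(1, -max_angle_deg, max_angle_deg)), tr)
}

random_points <- function(n, scale = 50) {
  matrix(runif(n * 3, -scale, scale), ncol = 3)
}

# Independent oracle for the rigid fit: numerical optimisation over
# an axis-angle parameterisation with the closed-form translation,
# started from several rotations to dodge local minima.
brute_force_rigid_fit <- function(src, tgt, starts = NULL) {
  obj <- function(par) {
    ang <- sqrt(sum(par^2))
    rot <- if (ang < 1e-12) diag(3) else rotation_about_axis(par, ang * 180 / pi)
    tr <- colMeans(tgt) - as.vector(rot %*% colMeans(src))
    sum((sweep(src %*% t(rot), 2, tr, `+`) - tgt)^2)
  }
  if (is.null(starts))
    starts <- list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2),
                   c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi), c(1.8, 1.8, 1.8))
  best <- NULL
  for (s in starts) {
    r <- optim(s, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-16,
                              ndeps = rep(1e-7, 3)))
    # polish from the incumbent until the parameters stop moving
    for (k in 1:3) {
      r2 <- optim(r$par, obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-16,
                                 ndeps = rep(1e-8, 3)))
      if (max(abs(r2$par - r$par)) < 1e-12) { r <- r2; break }
      r <- r2
    }
    if (is.null(best) || r$value < best$value) best <- r
  }
  ang <- sqrt(sum(best$par^2))
  rot <- if (ang < 1e-12) diag(3) else rotation_about_axis(best$par, ang * 180 / pi)
  tr <- colMeans(tgt) - as.vector(rot %*% colMeans(src))
  list(rotation = rot, translation = tr, rss = best$value)
}

# small rendering preset used across detection/calibration tests
render_default <- function(pose = rigid_transform(), noise_sd = 0, seed = NULL,
                           dims = c(192L, 192L, 192L), tm = make_tool_model()) {
  render_phantom_volume(tm, tool_pose = pose, noise_sd = noise_sd,
                        dims = dims, seed = seed)
}
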