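# Synthetic CBCT phantom: plastic slab + hollow fiducial spheres +
# soft-tissue lesions, with additive Gaussian noise. Spheres are
# rendered with antialiased (partial-volume) edges: each voxel blends
# between inside and outside level by the signed distance to the
# sphere surface over one voxel edge. That is what gives downstream
# centroiding its subvoxel accuracy, mirroring the partial-volume
# effect of a real reconstruction.

#' Default lesion set for the simulated phantom study
#'
#' Eight spherical soft-tissue targets, mirroring the abdominal
#' phantom's eight lesions. Positions are fixed (deterministic) inside
#' a 60 mm region; the real phantom's lesion coordinates and sizes are
#' not published, so these are invented stand-ins and the radius is a
#' parameter.
#'
#' @param radius_mm lesion radius, mm (default 5).
#' @return List of 8 lesions, each `list(center = <mm>, radius = <mm>)`.
#' @export
default_lesions <- function(radius_mm = 5) {
  centers <- matrix(c(
     18,  12, -20,
    -22,  18, -12,
     10, -24,  -8,
    -14, -16,  16,
     24,  -6,  12,
     -8,  26,   8,
      4,   8,  24,
    -26,  -8, -24
  ), ncol = 3, byrow = TRUE)
  lapply(seq_len(nrow(centers)),
         function(i) list(center = centers[i, ], radius = radius_mm))
}

# Paint an antialiased sphere into `vox` (modified in place by the
# caller via return value). Only the sphere's local bounding box is
# touched. `center_idx` is the 0-based (possibly fractional) index of
# the centre; `r_vox` the radius in voxels (isotropic spacing assumed
# for the blend width).
paint_sphere <- function(vox, center_idx, r_vox, level, blend_vox = 1) {
  d <- dim(vox)
  lo <- pmax(floor(center_idx - r_vox - blend_vox), 0)
  hi <- pmin(ceiling(center_idx + r_vox + blend_vox), d - 1)
  if (any(lo > hi)) return(vox)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- (ix - center_idx[1])^2
  dy2 <- (iy - center_idx[2])^2
  dz2 <- (iz - center_idx[3])^2
  rr <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  # occupancy: 1 well inside, 0 well outside, linear ramp across the surface
  f <- pmin(1, pmax(0, (r_vox - rr) / blend_vox + 0.5))
  sub <- vox[ix + 1, iy + 1, iz + 1, drop = FALSE]
  vox[ix + 1, iy + 1, iz + 1] <- sub * (1 - f) + level * f
  vox
}

#' Render a synthetic CBCT volume of the calibration phantom
#'
#' Produces the imaging-side input to the whole pipeline: a volume
#' containing a plastic slab with the tool's four hollow (air-density)
#' fiducial spheres at a given pose, optional soft-tissue lesions, and
#' additive Gaussian noise — together with the exact ground truth the
#' renderer used, so detection and calibration can be scored against
#' it.
#'
#' @param tool_model a [make_tool_model()] result.
#' @param tool_pose [rigid_transform()] mapping tool frame to image
#'   world (the quantity calibration must recover). Default identity.
#' @param lesions list of `list(center, radius)` in world mm (default
#'   none; see [default_lesions()]).
#' @param noise_sd additive Gaussian noise SD, HU-like units.
#' @param dims voxel counts per axis (default 192^3; use 288^3 or more
#'   when poses move the tool far from the volume centre).
#' @param spacing mm/voxel (default isotropic 0.48).
#' @param levels intensity levels: `background` (default 40, soft
#'   tissue), `slab` (default 100, plastic), `sphere` (default -1000,
#'   air inside the hollow spheres), `lesion` (default 70).
#' @param seed RNG seed for the noise (required when `noise_sd > 0`).
#' @return `list(volume = <volume_grid>, truth = <ground truth>)`;
#'   the truth carries `tool_pose`, `fiducial_centers_world` (always
#'   exactly `tool_pose` applied to the model fiducials), `lesions`,
#'   and the scan protocol metadata (200 degrees at 0.5 degrees/frame,
#'   397 projections, 6 s — carried verbatim as inert metadata).
#' @section Errors: signals `cbctnav_clipped` if any fiducial or
#'   lesion sphere would be cut by the volume boundary.
#' @export
render_phantom_volume <- function(tool_model, tool_pose = rigid_transform(),
                                  lesions = list(), noise_sd = 0,
                                  dims = c(192L, 192L, 192L),
                                  spacing = c(0.48, 0.48, 0.48),
                                  levels = list(), seed = NULL) {
  cbct_check(inherits(tool_model, "tool_model"), "cbctnav_validation",
             "tool_model must come from make_tool_model()")
  cbct_check(is_rigid_transform(tool_pose), "cbctnav_validation",
             "tool_pose must be a rigid_transform")
  cbct_check(noise_sd >= 0, "cbctnav_validation", "noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    cbct_abort("cbctnav_validation", "a seed is required when noise_sd > 0")
  lv <- utils::modifyList(list(background = 40, slab = 100,
                               sphere = -1000, lesion = 70), levels)
  dims <- as.integer(dims)
  spacing <- as_point3(spacing, "spacing")

  vox <- array(lv$background, dim = dims)
  vol <- volume_grid(vox, spacing = spacing)

  centers_world <- rt_apply(tool_pose, tool_model$fiducials)
  r_fid <- tool_model$sphere_radius

  # clip check in index space (spheres must sit wholly inside the grid)
  check_inside <- function(center, radius, what) {
    ci <- world_to_index(vol, center)
    r_vox <- radius / spacing
    if (any(ci - r_vox < 0) || any(ci + r_vox > dims - 1))
      cbct_abort("cbctnav_clipped", sprintf(
        "%s at (%.1f, %.1f, %.1f) mm with radius %.1f mm is clipped by the volume boundary",
        what, center[1], center[2], center[3], radius))
    ci
  }
  fid_idx <- t(vapply(seq_len(4), function(i)
    check_inside(centers_world[i, ], r_fid, sprintf("fiducial sphere %d", i)),
    numeric(3)))
  les_idx <- lapply(seq_along(lesions), function(i)
    check_inside(as_point3(lesions[[i]]$center), lesions[[i]]$radius,
                 sprintf("lesion %d", i)))

  # plastic slab: axis-aligned world box enclosing the spheres + margin
  slab_margin <- r_fid + 5
  slab_lo <- apply(centers_world, 2, min) - slab_margin
  slab_hi <- apply(centers_world, 2, max) + slab_margin
  ilo <- pmax(floor(world_to_index(vol, slab_lo)), 0)
  ihi <- pmin(ceiling(world_to_index(vol, slab_hi)), dims - 1)
  vox <- vol$voxels
  vox[(ilo[1]:ihi[1]) + 1, (ilo[2]:ihi[2]) + 1, (ilo[3]:ihi[3]) + 1] <- lv$slab

  for (i in seq_len(4))
    vox <- paint_sphere(vox, fid_idx[i, ], r_fid / spacing[1], lv$sphere)
  for (i in seq_along(lesions))
    vox <- paint_sphere(vox, les_idx[[i]], lesions[[i]]$radius / spacing[1],
                        lv$lesion)

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vox <- vox + array(rnorm(length(vox), 0, noise_sd), dim = dims)
  }
  vol$voxels <- vox

  truth <- structure(list(
    tool_pose = tool_pose,
    fiducial_centers_world = centers_world,
    lesions = lesions,
    scan_meta = list(rotation_deg = 200, deg_per_frame = 0.5,
                     n_projections = 397L, scan_time_s = 6),
    levels = lv, noise_sd = noise_sd
  ), class = "phantom_truth")

  list(volume = vol, truth = truth)
}
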