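#' Pairwise distance signature of a point set
#'
#' All `n(n-1)/2` pairwise Euclidean distances, sorted ascending. The
#' signature is invariant under rigid motion, which is what lets the
#' calibration tool's spheres be identified without any marker labels:
#' because the tool's four spheres sit at pairwise-unique distances,
#' the signature pins down which detected blob is which fiducial.
#'
#' @param points n x 3 matrix or list of 3-vectors, mm, n >= 2.
#' @return Numeric vector of distances, ascending, mm.
#' @export
distance_signature <- function(points) {
  pts <- as_points_matrix(points)
  cbct_check(nrow(pts) >= 2, "cbctnav_validation", "need at least 2 points")
  sort(as.vector(dist(pts)))
}

# Shipped fiducial coordinates (tool frame, mm, centred on the cloud
# centroid). Four points realising the pairwise distance set
# {11, 16.4, 21.8, 27.2, 32.6, 38} mm: adjacent signature gaps of
# 5.4 mm, chosen above the 5 mm minimum so the literal coordinates
# keep the margin, and an edge assignment picked for a well-spread
# tetrahedron (smallest principal extent ~6.6 mm) so the rigid fit is
# well conditioned about every axis. The real tool's in-tool sphere
# coordinates and diameters are not public; this geometry is invented
# and documented as such.
DEFAULT_TOOL_FIDUCIALS <- matrix(c(
    1.645121951, -10.235807791, -2.558185416,
   18.045121951, -10.235807791, -2.558185416,
   -8.067073171,   9.281191617, -2.558185416,
  -11.623170732,  11.190423966,  7.674556249
), ncol = 3, byrow = TRUE)

#' Construct a calibration-tool model
#'
#' The calibration tool is a radiotranslucent plastic slab containing
#' four hollow (air-density) spheres whose pairwise distances are all
#' different; the distance signature makes fiducial correspondence
#' unambiguous. `make_tool_model()` either returns the shipped default
#' geometry (deterministic, so downstream results are reproducible) or,
#' given a `seed`, draws a random configuration inside the bounding box
#' and keeps it only if the signature-gap requirement is met.
#'
#' @param fiducials optional 4 x 3 matrix of sphere centres (tool
#'   frame, mm). Default: the shipped geometry.
#' @param sphere_radius fiducial sphere radius, mm.
#' @param bounding_box tool extents (x, y, z), mm; the box is centred
#'   on the tool-frame origin. Default 200 x 75 x 30.
#' @param min_signature_gap smallest allowed absolute difference
#'   between any two pairwise distances, mm. Default 5.
#' @param seed if given (integer), draw a random configuration instead
#'   of using `fiducials`; required for randomised geometry so results
#'   are reproducible.
#' @param max_tries attempts for the randomised search.
#' @return A `tool_model`: list with `fiducials`, `sphere_radius`,
#'   `bounding_box`, `min_signature_gap`, `signature`.
#' @section Errors: signals `cbctnav_validation` if a configuration
#'   meeting the gap cannot be produced (the message reports the best
#'   gap achieved).
#' @examples
#' tm <- make_tool_model()
#' distance_signature(tm$fiducials)
#' @export
make_tool_model <- function(fiducials = NULL, sphere_radius = 4,
                            bounding_box = c(200, 75, 30),
                            min_signature_gap = 5,
                            seed = NULL, max_tries = 2000L) {
  bounding_box <- as_point3(bounding_box, "bounding_box")
  cbct_check(all(bounding_box > 0), "cbctnav_validation",
             "bounding box extents must be positive")
  cbct_check(sphere_radius > 0, "cbctnav_validation",
             "sphere_radius must be positive")

  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    half <- bounding_box / 2
    best_gap <- -Inf
    for (i in seq_len(max_tries)) {
      cand <- cbind(runif(4, -half[1], half[1]),
                    runif(4, -half[2], half[2]),
                    runif(4, -half[3], half[3]))
      sig <- distance_signature(cand)
      if (min(sig) < 2 * sphere_radius + 2) next   # spheres must not merge
      gap <- min(diff(sig))
      if (gap > best_gap) best_gap <- gap
      if (gap >= min_signature_gap) {
        fiducials <- sweep(cand, 2, colMeans(cand))
        break
      }
    }
    if (is.null(fiducials))
      cbct_abort("cbctnav_validation", sprintf(
        "no 4-point configuration with signature gap >= %.3g mm found in %d tries (best achieved: %.3g mm)",
        min_signature_gap, max_tries, best_gap))
  } else if (is.null(fiducials)) {
    fiducials <- DEFAULT_TOOL_FIDUCIALS
  }

  fiducials <- as_points_matrix(fiducials, "fiducials")
  cbct_check(nrow(fiducials) == 4, "cbctnav_validation",
             "the tool model has exactly 4 fiducial spheres")
  half <- bounding_box / 2
  cbct_check(all(abs(fiducials[, 1]) <= half[1]) &&
             all(abs(fiducials[, 2]) <= half[2]) &&
             all(abs(fiducials[, 3]) <= half[3]),
             "cbctnav_validation", "all fiducials must lie inside the bounding box")

  sig <- distance_signature(fiducials)
  gap <- min(diff(sig))
  if (gap <= 0)
    cbct_abort("cbctnav_validation",
               "pairwise distances must be mutually distinct (found two equal distances)")
  if (gap < min_signature_gap)
    cbct_abort("cbctnav_validation", sprintf(
      "pairwise distances are not unique enough: smallest signature gap %.4g mm < required %.4g mm",
      gap, min_signature_gap))

  structure(list(fiducials = fiducials,
                 sphere_radius = sphere_radius,
                 bounding_box = bounding_box,
                 min_signature_gap = min_signature_gap,
                 signature = sig),
            class = "tool_model")
}

#' @export
print.tool_model <- function(x, ...) {
  cat("tool_model: 4 fiducial spheres, radius", x$sphere_radius, "mm\n")
  cat("  distance signature (mm):", paste(round(x$signature, 2), collapse = ", "), "\n")
  cat("  bounding box (mm):", paste(x$bounding_box, collapse = " x "), "\n")
  invisible(x)
}
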