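# Blob detection for calibration spheres. The hollow fiducials are
# air (-1000) inside plastic (+100), so with the default threshold
# midway (-450) only sphere voxels survive thresholding even at high
# noise. Components are labelled with 26-connectivity (robust for
# small spheres at 0.48 mm voxels) and summarised by an
# intensity-weighted subvoxel centroid.

# 26-connected components over the TRUE voxels of a logical mask.
# Returns an integer label per mask voxel (in the order of which(mask)).
# Only mask voxels are materialised, so cost scales with blob volume,
# not grid volume; adjacency comes from matching linear indices over
# the 13 half-neighbourhood offsets, components from igraph.
label_components_26 <- function(mask, dims) {
  idx <- which(mask)                      # linear indices, 1-based
  if (length(idx) == 0L)
    return(list(idx = integer(0), labels = integer(0)))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i0 <- (idx - 1L) %% nx
  j0 <- ((idx - 1L) %/% nx) %% ny
  k0 <- (idx - 1L) %/% (nx * ny)
  pos <- integer(0); nbr <- integer(0)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[offs$dk > 0 | (offs$dk == 0 & (offs$dj > 0 | (offs$dj == 0 & offs$di > 0))), ]
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    ok <- ii >= 0L & ii < nx & jj >= 0L & jj < ny & kk >= 0L & kk < nz
    lin <- ii[ok] + nx * (jj[ok] + ny * kk[ok]) + 1L
    hit <- match(lin, idx)
    keep <- !is.na(hit)
    pos <- c(pos, which(ok)[keep])
    nbr <- c(nbr, hit[keep])
  }
  g <- igraph::make_graph(rbind(pos, nbr), n = length(idx), directed = FALSE)
  list(idx = idx, labels = igraph::components(g)$membership)
}

#' Detect candidate fiducial spheres in a volume
#'
#' Thresholds the volume (`<= threshold` for `polarity = "dark"`,
#' `>= threshold` for `"bright"`), labels 26-connected components,
#' filters them by voxel count and equivalent-sphere radius, and
#' returns intensity-weighted subvoxel centroids in world mm, sorted
#' by blob size descending. Finding nothing is an empty list, not an
#' error.
#'
#' @param volume a [volume_grid()].
#' @param polarity `"dark"` (air spheres, the default) or `"bright"`.
#' @param threshold intensity cut, HU-like; default -450, midway
#'   between air (-1000) and the plastic slab (+100).
#' @param min_blob_voxels smallest accepted component (default 10,
#'   rejects noise specks).
#' @param r_range accepted equivalent radius `(min, max)` in mm
#'   (default `c(1.5, 8)`, excludes specks and lesions).
#' @return List of candidates: `centroid_world` (mm), `voxel_count`,
#'   `mean_intensity`, `equivalent_radius` (mm of the equal-volume
#'   sphere).
#' @export
detect_candidates <- function(volume, polarity = c("dark", "bright"),
                              threshold = -450, min_blob_voxels = 10L,
                              r_range = c(1.5, 8)) {
  cbct_check(inherits(volume, "volume_grid"), "cbctnav_validation",
             "volume must be a volume_grid")
  polarity <- match.arg(polarity)
  dims <- dim(volume$voxels)
  vals <- volume$voxels
  mask <- if (polarity == "dark") vals <= threshold else vals >= threshold
  lab <- label_components_26(mask, dims)
  if (length(lab$idx) == 0L) return(list())

  vv <- prod(volume$spacing)              # voxel volume, mm^3
  v <- vals[lab$idx]
  # weights: contrast against the threshold, always >= 0
  w <- if (polarity == "dark") threshold - v else v - threshold
  w <- pmax(w, 0)
  i0 <- (lab$idx - 1L) %% dims[1]
  j0 <- ((lab$idx - 1L) %/% dims[1]) %% dims[2]
  k0 <- (lab$idx - 1L) %/% (dims[1] * dims[2])

  out <- list()
  for (lbl in seq_len(max(lab$labels))) {
    sel <- lab$labels == lbl
    n <- sum(sel)
    if (n < min_blob_voxels) next
    r_eq <- (3 * n * vv / (4 * pi))^(1 / 3)
    if (r_eq < r_range[1] || r_eq > r_range[2]) next
    ws <- w[sel]
    tw <- sum(ws)
    ci <- if (tw > 0) {
      c(sum(ws * i0[sel]), sum(ws * j0[sel]), sum(ws * k0[sel])) / tw
    } else {
      c(mean(i0[sel]), mean(j0[sel]), mean(k0[sel]))
    }
    out[[length(out) + 1L]] <- list(
      centroid_world = index_to_world(volume, ci),
      voxel_count = n,
      mean_intensity = mean(v[sel]),
      equivalent_radius = r_eq)
  }
  out[order(vapply(out, `[[`, integer(1), "voxel_count"), decreasing = TRUE)]
}

#' Refine a blob centroid on a local window
#'
#' Recomputes the intensity-weighted centroid on a background-subtracted
#' cubic window around a candidate. The window is aligned to the voxel
#' grid (centred on the rounded candidate index), so a refinement that
#' moves the centre by less than half a voxel is exactly idempotent.
#' Background is taken as the median of the window's boundary shell.
#'
#' @param volume a [volume_grid()].
#' @param candidate a candidate from [detect_candidates()] (or any
#'   list with `centroid_world`).
#' @param window_mm window radius, mm (default 6): weights are
#'   supported on the ball of this radius, so nearby blobs (the
#'   closest fiducial pair is 11 mm apart) cannot bias the centroid.
#' @param polarity `"dark"` or `"bright"`, as in [detect_candidates()].
#' @return Refined centroid, world mm.
#' @section Errors: signals `cbctnav_validation` if the window exits
#'   the volume bounds.
#' @export
refine_centroid <- function(volume, candidate, window_mm = 6,
                            polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  center <- as_point3(candidate$centroid_world, "centroid_world")
  dims <- dim(volume$voxels)
  ci <- round(world_to_index(volume, center))
  hw <- ceiling(window_mm / volume$spacing)
  lo <- ci - hw; hi <- ci + hw
  if (any(lo < 0) || any(hi > dims - 1))
    cbct_abort("cbctnav_validation", "refinement window exits the volume bounds")
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  sub <- volume$voxels[ix + 1, iy + 1, iz + 1, drop = FALSE]
  bg <- median(sub[!slice_interior(dim(sub))])  # boundary shell
  w <- if (polarity == "dark") bg - sub else sub - bg
  w <- pmax(w, 0)
  # keep only the blob core: the window may straddle tissue/slab
  # interfaces whose moderate contrast would otherwise bias the centroid
  w[w < 0.5 * max(w)] <- 0
  # spherical support about the window centre (grid-symmetric)
  dx2 <- ((ix - ci[1]) * volume$spacing[1])^2
  dy2 <- ((iy - ci[2]) * volume$spacing[2])^2
  dz2 <- ((iz - ci[3]) * volume$spacing[3])^2
  rball <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  w[rball > window_mm] <- 0
  tw <- sum(w)
  cbct_check(tw > 0, "cbctnav_validation",
             "window contains no signal above background")
  gx <- outer(outer(ix, rep(1, length(iy))), rep(1, length(iz)))
  gy <- outer(outer(rep(1, length(ix)), iy), rep(1, length(iz)))
  gz <- outer(outer(rep(1, length(ix)), rep(1, length(iy))), iz)
  ci_ref <- c(sum(w * gx), sum(w * gy), sum(w * gz)) / tw
  index_to_world(volume, ci_ref)
}

# logical array marking the interior (non-boundary) voxels of a block
slice_interior <- function(d) {
  a <- array(FALSE, d)
  if (all(d >= 3)) a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  a
}
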