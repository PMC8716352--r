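#' 3D scalar volume with spacing, origin and orientation
#'
#' The in-memory stand-in for a CBCT reconstruction: a 3D array of
#' HU-like intensities plus the geometry needed to map voxel indices to
#' world coordinates. The world frame is LPS, mm; indices are 0-based;
#' `world = origin + direction %*% (index * spacing)`.
#'
#' @param voxels 3D numeric array.
#' @param spacing mm per voxel along each axis (default isotropic 0.48,
#'   the control-scan resolution the pipeline is designed around).
#' @param origin world coordinate of voxel (0, 0, 0), mm. Default
#'   centres the volume on the world origin.
#' @param direction 3x3 orthonormal axis matrix (columns = world
#'   directions of the voxel axes).
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(voxels, spacing = c(0.48, 0.48, 0.48),
                        origin = NULL, direction = diag(3)) {
  cbct_check(is.array(voxels) && length(dim(voxels)) == 3,
             "cbctnav_validation", "voxels must be a 3D array")
  spacing <- as_point3(spacing, "spacing")
  cbct_check(all(spacing > 0), "cbctnav_validation", "spacing must be > 0 on all axes")
  direction <- as.matrix(direction)
  storage.mode(direction) <- "double"
  cbct_check(all(dim(direction) == c(3, 3)) &&
             max(abs(crossprod(direction) - diag(3))) < 1e-9 &&
             abs(abs(det(direction)) - 1) < 1e-9,
             "cbctnav_validation", "direction must be a 3x3 orthonormal matrix")
  if (is.null(origin)) origin <- -as.vector(direction %*% ((dim(voxels) - 1) / 2 * spacing))
  origin <- as_point3(origin, "origin")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = origin, direction = direction),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume_grid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(round(x$spacing, 4), collapse = " x ")))
  cat("  origin (mm):", paste(round(x$origin, 3), collapse = ", "), "\n")
  cat("  intensity range:", paste(round(range(x$voxels), 1), collapse = " .. "), "\n")
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Indices are 0-based and may be fractional (subvoxel positions).
#'
#' @param volume a [volume_grid()].
#' @param index n x 3 matrix (or 3-vector) of 0-based indices.
#' @param world n x 3 matrix (or 3-vector) of world coordinates, mm.
#' @return The converted coordinates, matching the input shape.
#' @export
index_to_world <- function(volume, index) {
  one <- is.null(dim(index))
  idx <- if (one) matrix(as.numeric(index), 1) else as_points_matrix(index, "index")
  w <- sweep(sweep(idx, 2, volume$spacing, `*`) %*% t(volume$direction),
             2, volume$origin, `+`)
  if (one) as.vector(w) else w
}

#' @rdname index_to_world
#' @export
world_to_index <- function(volume, world) {
  one <- is.null(dim(world))
  w <- if (one) matrix(as.numeric(world), 1) else as_points_matrix(world, "world")
  idx <- sweep(sweep(w, 2, volume$origin, `-`) %*% volume$direction,
               2, volume$spacing, `/`)
  if (one) as.vector(idx) else idx
}

#' Read and write volumes
#'
#' Volumes are stored either as NIfTI (`.nii` / `.nii.gz`; geometry in
#' the sform, which carries this package's LPS world frame directly) or
#' as raw little-endian float32 with a JSON sidecar
#' (`{shape, spacing, origin, direction}`; sidecar path = `<file>.json`).
#'
#' @param volume a [volume_grid()].
#' @param path output path; format chosen by extension (`.nii`,
#'   `.nii.gz`, otherwise raw + JSON sidecar).
#' @return `write_volume` returns `path` invisibly; `read_volume`
#'   returns a [volume_grid()].
#' @export
write_volume <- function(volume, path) {
  cbct_check(inherits(volume, "volume_grid"), "cbctnav_validation",
             "volume must be a volume_grid")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    m <- diag(4)
    m[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
    m[1:3, 4] <- volume$origin
    img <- RNifti::asNifti(volume$voxels)
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$voxels), con, size = 4L, endian = "little")
    jsonlite::write_json(list(shape = dim(volume$voxels),
                              spacing = volume$spacing,
                              origin = volume$origin,
                              direction = volume$direction),
                         paste0(path, ".json"),
                         auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    m <- RNifti::xform(img)
    a <- m[1:3, 1:3]
    spacing <- sqrt(colSums(a^2))
    volume_grid(array(as.numeric(img), dim = dim(img)),
                spacing = spacing,
                origin = m[1:3, 4],
                direction = sweep(a, 2, spacing, `/`))
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    vox <- readBin(con, "numeric", n = prod(shape), size = 4L, endian = "little")
    dirm <- meta$direction
    if (!is.matrix(dirm)) dirm <- matrix(unlist(dirm), 3, 3, byrow = TRUE)
    volume_grid(array(vox, dim = shape),
                spacing = as.numeric(meta$spacing),
                origin = as.numeric(meta$origin),
                direction = dirm)
  }
}
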