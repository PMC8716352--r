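# JSON schemas for the pipeline's artifacts. All lengths mm, all
# angles degrees; matrices row-major. Every writer/reader pair
# round-trips: read(write(x)) reproduces x.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", pretty = TRUE)
  invisible(path)
}

read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

as_mat3 <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(unlist(x), ncol = 3, byrow = !is.matrix(x))
}

#' Read and write pipeline artifacts as JSON
#'
#' Serialization for the tool model, ground truth, rigid transforms /
#' calibration results, trajectory plans and study reports. Schemas
#' use mm and degrees throughout; transforms are stored as 4x4
#' homogeneous matrices in row-major order.
#'
#' @param x the artifact.
#' @param path file path.
#' @return Writers return `path` invisibly; readers return the
#'   reconstructed object.
#' @name artifact_json
NULL

#' @rdname artifact_json
#' @export
write_tool_model <- function(x, path) {
  write_json_file(list(kind = "tool_model",
                       fiducials_mm = x$fiducials,
                       sphere_radius_mm = x$sphere_radius,
                       bounding_box_mm = x$bounding_box,
                       min_signature_gap_mm = x$min_signature_gap), path)
}

#' @rdname artifact_json
#' @export
read_tool_model <- function(path) {
  j <- read_json_file(path)
  make_tool_model(fiducials = as_mat3(j$fiducials_mm),
                  sphere_radius = j$sphere_radius_mm,
                  bounding_box = j$bounding_box_mm,
                  min_signature_gap = j$min_signature_gap_mm)
}

rt_to_homogeneous <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname artifact_json
#' @export
write_transform <- function(x, path) {
  write_json_file(list(kind = "rigid_transform",
                       matrix = rt_to_homogeneous(x)), path)
}

#' @rdname artifact_json
#' @export
read_transform <- function(path) {
  j <- read_json_file(path)
  m <- j$matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @rdname artifact_json
#' @export
write_ground_truth <- function(x, path) {
  write_json_file(list(kind = "ground_truth",
                       tool_pose = rt_to_homogeneous(x$tool_pose),
                       fiducial_centers_world_mm = x$fiducial_centers_world,
                       lesions = lapply(x$lesions, function(l)
                         list(center_mm = l$center, radius_mm = l$radius)),
                       scan_meta = x$scan_meta), path)
}

#' @rdname artifact_json
#' @export
read_ground_truth <- function(path) {
  j <- read_json_file(path)
  m <- j$tool_pose
  if (!is.matrix(m)) m <- matrix(unlist(m), 4, 4, byrow = TRUE)
  lesions <- j$lesions
  if (is.data.frame(lesions)) {
    lesions <- lapply(seq_len(nrow(lesions)), function(i)
      list(center = unlist(lesions$center_mm[i]), radius = lesions$radius_mm[i]))
  } else if (is.list(lesions)) {
    lesions <- lapply(lesions, function(l)
      list(center = as.numeric(unlist(l$center_mm)), radius = l$radius_mm))
  }
  structure(list(tool_pose = rigid_transform(m[1:3, 1:3], m[1:3, 4]),
                 fiducial_centers_world = as_mat3(j$fiducial_centers_world_mm),
                 lesions = lesions,
                 scan_meta = j$scan_meta),
            class = "phantom_truth")
}

#' @rdname artifact_json
#' @export
write_calibration <- function(x, path) {
  write_json_file(list(kind = "calibration_result",
                       image_to_tool = rt_to_homogeneous(x$transform),
                       correspondence = x$correspondence,
                       fre_mm = x$fre_mm,
                       n_candidates = x$n_candidates,
                       ambiguity_ratio = if (is.finite(x$ambiguity_ratio))
                         x$ambiguity_ratio else "unique"), path)
}

#' @rdname artifact_json
#' @export
read_calibration <- function(path) {
  j <- read_json_file(path)
  m <- j$image_to_tool
  if (!is.matrix(m)) m <- matrix(unlist(m), 4, 4, byrow = TRUE)
  tf <- rigid_transform(m[1:3, 1:3], m[1:3, 4])
  structure(list(transform = tf, tool_pose = rt_inverse(tf),
                 correspondence = as.integer(j$correspondence),
                 fre_mm = j$fre_mm, n_candidates = j$n_candidates,
                 ambiguity_ratio = if (identical(j$ambiguity_ratio, "unique"))
                   Inf else as.numeric(j$ambiguity_ratio)),
            class = "calibration_result")
}

#' @rdname artifact_json
#' @export
write_plan <- function(x, path) {
  write_json_file(list(kind = "trajectory_plan",
                       entry_mm = x$entry_A, target_mm = x$target_B,
                       depth_mm = x$depth_mm,
                       craniocaudal_deg = x$craniocaudal_deg,
                       raolao_deg = x$raolao_deg,
                       plane_class = x$plane_class,
                       reachable = x$reachable), path)
}

#' @rdname artifact_json
#' @export
read_plan <- function(path) {
  j <- read_json_file(path)
  plan_trajectory(as.numeric(j$entry_mm), as.numeric(j$target_mm))
}

#' @rdname artifact_json
#' @export
write_candidates <- function(x, path) {
  write_json_file(list(kind = "fiducial_candidates",
                       candidates = lapply(x, function(cc)
                         list(centroid_world_mm = cc$centroid_world,
                              voxel_count = cc$voxel_count,
                              mean_intensity = cc$mean_intensity,
                              equivalent_radius_mm = cc$equivalent_radius))),
                  path)
}

#' @rdname artifact_json
#' @export
read_candidates <- function(path) {
  j <- read_json_file(path)
  cc <- j$candidates
  if (is.data.frame(cc)) {
    lapply(seq_len(nrow(cc)), function(i)
      list(centroid_world = as.numeric(unlist(cc$centroid_world_mm[i])),
           voxel_count = cc$voxel_count[i],
           mean_intensity = cc$mean_intensity[i],
           equivalent_radius = cc$equivalent_radius_mm[i]))
  } else {
    lapply(cc, function(one)
      list(centroid_world = as.numeric(unlist(one$centroid_world_mm)),
           voxel_count = one$voxel_count,
           mean_intensity = one$mean_intensity,
           equivalent_radius = one$equivalent_radius_mm))
  }
}

#' @rdname artifact_json
#' @export
write_study_report <- function(x, path) {
  metrics <- lapply(x$metrics, function(m)
    lapply(m, function(el) if (is.null(el)) NULL else unclass(el)))
  write_json_file(list(kind = "study_report",
                       n_outcomes = x$n_outcomes,
                       success_rate = x$success_rate,
                       metrics = metrics,
                       per_needle = x$per_needle), path)
}
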