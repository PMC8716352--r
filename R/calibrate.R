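# Correspondence-free fiducial matching + end-to-end calibration.
# Because the tool's four spheres sit at pairwise-unique distances,
# the 6-element distance signature identifies the true 4-subset of
# detected blobs and the assignment of blobs to model spheres; a
# closed-form rigid fit then yields the robot-to-image transform.

#' Match detected candidates to the tool's fiducials
#'
#' Brute-force correspondence search: enumerates every 4-subset of the
#' candidates and every assignment (permutation) of the subset to the
#' four model fiducials, keeps assignments whose six pairwise
#' distances each agree with the model's within `dist_tol_mm`, and
#' returns the one minimising the post-fit fiducial registration
#' error. With at most 20 candidates the search space is
#' C(20,4) * 4! = 116,280 assignments — trivially enumerable, and
#' exhaustive enumeration is what makes correctness checkable.
#'
#' @param candidates list from [detect_candidates()], or an n x 3
#'   matrix of points (mm). If more than `max_candidates`, the largest
#'   blobs are kept.
#' @param tool_model a [make_tool_model()] result.
#' @param dist_tol_mm per-distance tolerance, mm. Default 0.96 (two
#'   voxel edges): centroid error is bounded by about half a voxel per
#'   point.
#' @param max_candidates cap before enumeration (default 20).
#' @return `list(correspondence, fre_mm, transform, ambiguity_ratio,
#'   n_candidates)`: `correspondence[i]` is the candidate index
#'   matched to model fiducial `i`; `transform` maps tool frame to
#'   the candidates' frame; `ambiguity_ratio` is FRE(best)/FRE(second
#'   best matching assignment), `Inf` when the match is unique.
#' @section Errors: `cbctnav_no_match` when no assignment satisfies
#'   the tolerance; `cbctnav_ambiguous` when a runner-up assignment
#'   also passes and its FRE is within 1.5x of the best
#'   (`ambiguity_ratio > 0.67`).
#' @export
match_fiducials <- function(candidates, tool_model, dist_tol_mm = 0.96,
                            max_candidates = 20L) {
  pts <- if (is.list(candidates) && !is.null(candidates[[1]]$centroid_world)) {
    do.call(rbind, lapply(candidates, `[[`, "centroid_world"))
  } else {
    as_points_matrix(candidates, "candidates")
  }
  cbct_check(nrow(pts) >= 4, "cbctnav_validation",
             "need at least 4 candidates to match 4 fiducials")
  n_all <- nrow(pts)
  if (n_all > max_candidates) pts <- pts[seq_len(max_candidates), , drop = FALSE]
  n <- nrow(pts)

  model <- tool_model$fiducials
  dmodel <- as.matrix(dist(model))
  dcand <- as.matrix(dist(pts))

  perms <- list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
                c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
                c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
                c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  pair_idx <- utils::combn(4, 2)

  hits <- list()
  subsets <- utils::combn(n, 4)
  for (s in seq_len(ncol(subsets))) {
    sub <- subsets[, s]
    dsub <- dcand[sub, sub]
    # cheap prefilter: the sorted signatures must agree within tolerance
    if (max(abs(sort(dsub[upper.tri(dsub)]) - tool_model$signature)) > dist_tol_mm)
      next
    for (p in perms) {
      # assignment: candidate sub[p[i]] plays model fiducial i
      ok <- TRUE
      for (q in seq_len(ncol(pair_idx))) {
        a <- pair_idx[1, q]; b <- pair_idx[2, q]
        if (abs(dsub[p[a], p[b]] - dmodel[a, b]) > dist_tol_mm) { ok <- FALSE; break }
      }
      if (!ok) next
      cand_pts <- pts[sub[p], , drop = FALSE]
      fit <- tryCatch(fit_rigid_transform(model, cand_pts), error = function(e) NULL)
      if (is.null(fit)) next
      fre <- fiducial_registration_error(fit, model, cand_pts)
      hits[[length(hits) + 1L]] <- list(correspondence = sub[p], fre_mm = fre,
                                        transform = fit)
    }
  }
  if (length(hits) == 0L)
    cbct_abort("cbctnav_no_match", sprintf(
      "no 4-subset of %d candidates matches the tool's distance signature within %.3g mm",
      n, dist_tol_mm))

  fres <- vapply(hits, `[[`, numeric(1), "fre_mm")
  ord <- order(fres)
  best <- hits[[ord[1]]]
  ratio <- Inf
  if (length(hits) >= 2L) {
    f1 <- fres[ord[1]]; f2 <- fres[ord[2]]
    ratio <- if (f2 > 0) f1 / f2 else 1
    if (ratio > 0.67)
      cbct_abort("cbctnav_ambiguous", sprintf(
        "correspondence is ambiguous: runner-up assignment FRE %.4g mm is within 1.5x of best %.4g mm",
        f2, f1))
  }
  list(correspondence = best$correspondence, fre_mm = best$fre_mm,
       transform = best$transform, ambiguity_ratio = ratio,
       n_candidates = n_all)
}

#' Robot-to-image calibration from a volume
#'
#' The full calibration pipeline of the guided workflow: detect
#' candidate spheres, identify the tool's four fiducials by distance
#' signature, fit the rigid transform, report the fiducial
#' registration error. Deterministic on fixed input.
#'
#' @param volume a [volume_grid()] containing the rendered (or
#'   acquired) calibration tool.
#' @param tool_model a [make_tool_model()] result.
#' @param polarity,threshold,min_blob_voxels,r_range passed to
#'   [detect_candidates()].
#' @param dist_tol_mm passed to [match_fiducials()].
#' @return A `calibration_result`: `transform` (image world -> tool
#'   frame), `tool_pose` (its inverse, tool -> image world),
#'   `correspondence`, `fre_mm`, `n_candidates`, `ambiguity_ratio`.
#' @section Errors: propagates `cbctnav_no_match` /
#'   `cbctnav_ambiguous` / `cbctnav_degenerate_geometry` from the
#'   stages, each message prefixed with the stage name.
#' @export
calibrate <- function(volume, tool_model, polarity = "dark",
                      threshold = -450, min_blob_voxels = 10L,
                      r_range = c(1.5, 8), dist_tol_mm = 0.96) {
  cands <- detect_candidates(volume, polarity = polarity, threshold = threshold,
                             min_blob_voxels = min_blob_voxels, r_range = r_range)
  if (length(cands) < 4)
    cbct_abort("cbctnav_no_match", sprintf(
      "detection stage: found only %d candidate blob(s); need 4 fiducials",
      length(cands)))
  m <- withCallingHandlers(
    match_fiducials(cands, tool_model, dist_tol_mm = dist_tol_mm),
    cbctnav_error = function(e) {
      e$message <- paste0("matching stage: ", conditionMessage(e))
      stop(e)
    })
  structure(list(transform = rt_inverse(m$transform),
                 tool_pose = m$transform,
                 correspondence = m$correspondence,
                 fre_mm = m$fre_mm,
                 n_candidates = m$n_candidates,
                 ambiguity_ratio = m$ambiguity_ratio,
                 candidates = cands),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result\n")
  cat(sprintf("  FRE: %.4f mm over 4 fiducials (%d candidates, ambiguity ratio %s)\n",
              x$fre_mm, x$n_candidates,
              if (is.finite(x$ambiguity_ratio)) sprintf("%.3g", x$ambiguity_ratio) else "unique"))
  cat("  tool pose (tool -> image):\n")
  print(x$tool_pose)
  invisible(x)
}
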