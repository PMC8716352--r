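test_that("noise-free default phantom yields exactly 4 subvoxel-accurate candidates", {
  ph <- render_default()
  cands <- detect_candidates(ph$volume)
  expect_length(cands, 4)
  truth <- ph$truth$fiducial_centers_world
  for (cc in cands) {
    d <- sqrt(rowSums(sweep(truth, 2, cc$centroid_world)^2))
    expect_lt(min(d), 0.25)  # within half a voxel
    expect_gte(cc$voxel_count, 10)
    expect_gte(cc$equivalent_radius, 1.5)
    expect_lte(cc$equivalent_radius, 8)
  }
})

test_that("a pure-background volume yields an empty candidate list", {
  vol <- volume_grid(array(40, c(32, 32, 32)))
  expect_identical(detect_candidates(vol), list())
})

test_that("detection stays accurate under noise (Monte-Carlo against truth)", {
  tm <- make_tool_model()
  truth0 <- NULL
  for (rep in 1:20) {
    ph <- render_phantom_volume(tm, noise_sd = 20, dims = c(128L, 128L, 128L),
                                seed = 400 + rep)
    cands <- detect_candidates(ph$volume)
    expect_gte(length(cands), 4)
    top4 <- do.call(rbind, lapply(cands[1:4], `[[`, "centroid_world"))
    truth <- ph$truth$fiducial_centers_world
    for (i in 1:4) {
      d <- sqrt(rowSums(sweep(top4, 2, truth[i, ])^2))
      expect_lt(min(d), 0.48)  # within one voxel edge
    }
  }
})

test_that("centroids are translation-equivariant for integer-voxel shifts", {
  tm <- make_tool_model()
  shift_vox <- c(5L, -3L, 2L)
  shift_mm <- shift_vox * 0.48
  ph0 <- render_default(tm = tm)
  ph1 <- render_phantom_volume(tm, tool_pose = rigid_transform(translation = shift_mm))
  c0 <- detect_candidates(ph0$volume)
  c1 <- detect_candidates(ph1$volume)
  expect_length(c1, 4)
  # order by matching against truth to pair candidates across scenes
  pair <- function(cands, truth) {
    t(vapply(seq_len(nrow(truth)), function(i) {
      pts <- do.call(rbind, lapply(cands, `[[`, "centroid_world"))
      pts[which.min(rowSums(sweep(pts, 2, truth[i, ])^2)), ]
    }, numeric(3)))
  }
  p0 <- pair(c0, ph0$truth$fiducial_centers_world)
  p1 <- pair(c1, ph1$truth$fiducial_centers_world)
  expect_lt(max(abs(p1 - sweep(p0, 2, -shift_mm))), 1e-9)
})

test_that("full fiducial recall holds across 100 seeded noisy runs", {
  tm <- make_tool_model()
  ok <- 0L
  for (rep in 1:100) {
    noise <- (rep %% 3 + 1) * 10  # 10, 20, 30 — up to the stated ceiling
    ph <- render_phantom_volume(tm, noise_sd = noise, seed = 7000 + rep)
    cands <- detect_candidates(ph$volume)
    if (length(cands) < 4) next
    top4 <- do.call(rbind, lapply(cands[1:4], `[[`, "centroid_world"))
    truth <- ph$truth$fiducial_centers_world
    hit <- all(vapply(seq_len(4), function(i)
      min(sqrt(rowSums(sweep(top4, 2, truth[i, ])^2))) < 0.48, logical(1)))
    if (hit) ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})

test_that("centroid refinement is exact on symmetric input and idempotent", {
  tm <- make_tool_model()
  ph <- render_default(tm = tm)
  vol <- ph$volume
  # a sphere centered exactly on a voxel center: symmetric window
  center_idx <- round(world_to_index(vol, c(30, 30, 30)))
  center_world <- index_to_world(vol, center_idx)
  vol2 <- vol
  vol2$voxels <- cbctnav:::paint_sphere(array(40, dim(vol$voxels)),
                                        center_idx, 4 / 0.48, -1000)
  cand <- list(centroid_world = center_world + c(0.1, -0.1, 0.05))
  refined <- refine_centroid(vol2, cand)
  expect_equal(refined, center_world, tolerance = 1e-9)

  # real (asymmetrically sampled) fiducial: refinement is a fixed point
  cands <- detect_candidates(vol)
  r1 <- refine_centroid(vol, cands[[1]])
  r2 <- refine_centroid(vol, list(centroid_world = r1))
  expect_lt(max(abs(r2 - r1)), 1e-6)
})

test_that("refinement recovers centers placed between voxels within 0.1 mm", {
  base <- array(40, c(64, 64, 64))
  vol <- volume_grid(base)
  center_idx <- c(31.5, 31.5, 31.5)  # halfway between voxel centers
  vol$voxels <- cbctnav:::paint_sphere(base, center_idx, 4 / 0.48, -1000)
  truth <- index_to_world(vol, center_idx)
  cand <- detect_candidates(vol)[[1]]
  refined <- refine_centroid(vol, cand)
  expect_lt(sqrt(sum((refined - truth)^2)), 0.1)
})

test_that("a window leaving the volume is refused", {
  vol <- volume_grid(array(40, c(32, 32, 32)))
  cand <- list(centroid_world = index_to_world(vol, c(1, 1, 1)))
  expect_error(refine_centroid(vol, cand, window_mm = 8),
               class = "cbctnav_validation")
})

test_that("bright polarity detects bright blobs", {
  base <- array(0, c(48, 48, 48))
  vol <- volume_grid(base)
  vol$voxels <- cbctnav:::paint_sphere(base, c(24, 24, 24), 3 / 0.48, 500)
  cands <- detect_candidates(vol, polarity = "bright", threshold = 250)
  expect_length(cands, 1)
  expect_lt(sqrt(sum((cands[[1]]$centroid_world -
                        index_to_world(vol, c(24, 24, 24)))^2)), 0.25)
})
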