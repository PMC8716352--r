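test_that("CRC-64 matches the published ECMA-182 check value", {
  # standard check input "123456789" -> 0x6C40DF5F0B497347
  expect_identical(
    paste(sprintf("%02X", as.integer(crc64(charToRaw("123456789")))), collapse = ""),
    "6C40DF5F0B497347")
  expect_identical(crc64(raw(0)), as.raw(rep(0, 8)))
})

test_that("transform messages round-trip within float32 precision", {
  set.seed(71)
  for (i in 1:100) {
    tf <- random_rigid()
    msg <- encode_transform_message(tf, "dev", i)
    dec <- decode_transform_message(msg)
    expect_lt(max(abs(dec$transform$rotation - tf$rotation)), 1e-6)
    expect_lt(max(abs(dec$transform$translation - tf$translation)), 1e-4)
    expect_identical(dec$device_name, "dev")
    expect_equal(dec$timestamp, i)
  }
  # identity body floats
  msg <- encode_transform_message(rigid_transform(), "id")
  body <- msg[-(1:58)]
  floats <- readBin(body, "numeric", n = 12, size = 4, endian = "big")
  expect_identical(floats, c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0))
  expect_identical(length(msg), 106L)  # 58-byte header + 48-byte body
})

test_that("corruption is always detected", {
  set.seed(73)
  tf <- random_rigid()
  msg <- encode_transform_message(tf, "dev")
  for (rep in 1:20) {
    m2 <- msg
    pos <- sample(59:length(msg), 1)          # body byte
    bit <- as.raw(2^sample(0:7, 1))
    m2[pos] <- xor(m2[pos], bit)
    expect_error(decode_transform_message(m2), class = "cbctnav_crc_mismatch")
  }
  # corrupted body_size -> truncated
  m3 <- msg
  m3[50] <- xor(m3[50], as.raw(1))
  expect_error(decode_transform_message(m3), class = "cbctnav_truncated")
  # short read
  expect_error(decode_transform_message(msg[1:40]), class = "cbctnav_truncated")
  # wrong type for the decoder
  pm <- encode_point_message(c(1, 2, 3))
  expect_error(decode_transform_message(pm), class = "cbctnav_unknown_type")
})

test_that("point messages round-trip and support replanning", {
  pm <- encode_point_message(c(0, 0, 0))
  expect_identical(decode_point_message(pm)$points, matrix(c(0, 0, 0), 1))

  a <- c(1.5, -22.25, 3); b <- c(10, 80.5, -6)
  msg <- encode_point_message(rbind(a, b), "plan")
  pts <- decode_point_message(msg)$points
  p0 <- plan_trajectory(a, b)
  p1 <- plan_trajectory(pts[1, ], pts[2, ])
  expect_identical(p1$depth_mm, p0$depth_mm)       # coordinates chosen float32-exact
  expect_identical(p1$direction_u, p0$direction_u)
})

test_that("JSON artifacts round-trip", {
  dir <- withr::local_tempdir()
  tm <- make_tool_model()
  f <- file.path(dir, "tool.json")
  write_tool_model(tm, f)
  tm2 <- read_tool_model(f)
  expect_equal(tm2$fiducials, tm$fiducials, tolerance = 1e-12)
  expect_equal(tm2$signature, tm$signature, tolerance = 1e-12)

  set.seed(83)
  tf <- random_rigid()
  f <- file.path(dir, "tf.json")
  write_transform(tf, f)
  tf2 <- read_transform(f)
  expect_equal(tf2$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(tf2$translation, tf$translation, tolerance = 1e-12)

  pose <- rigid_transform(rotation_about_axis(c(1, 1, 0), 10), c(5, -4, 3))
  ph <- render_phantom_volume(tm, tool_pose = pose,
                              lesions = default_lesions(),
                              dims = c(192L, 192L, 192L))
  f <- file.path(dir, "truth.json")
  write_ground_truth(ph$truth, f)
  gt <- read_ground_truth(f)
  expect_equal(gt$fiducial_centers_world, ph$truth$fiducial_centers_world,
               tolerance = 1e-12)
  expect_equal(gt$tool_pose$rotation, pose$rotation, tolerance = 1e-12)
  expect_length(gt$lesions, 8)
  expect_equal(gt$scan_meta$n_projections, 397)

  plan <- plan_trajectory(c(1, 2, 3), c(4, 50, 6))
  f <- file.path(dir, "plan.json")
  write_plan(plan, f)
  plan2 <- read_plan(f)
  expect_equal(plan2$depth_mm, plan$depth_mm, tolerance = 1e-12)
  expect_equal(plan2$craniocaudal_deg, plan$craniocaudal_deg, tolerance = 1e-12)
})

test_that("volumes round-trip through NIfTI and raw-plus-sidecar", {
  dir <- withr::local_tempdir()
  set.seed(89)
  vol <- volume_grid(array(rnorm(16^3, 40, 5), c(16, 16, 16)),
                     origin = c(-10, 4, 2.5))
  for (name in c("v.nii.gz", "v.raw")) {
    f <- file.path(dir, name)
    write_volume(vol, f)
    v2 <- read_volume(f)
    expect_equal(v2$voxels, vol$voxels, tolerance = 1e-5)  # float32 storage
    expect_equal(v2$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, vol$origin, tolerance = 1e-5)
    expect_equal(v2$direction, vol$direction, tolerance = 1e-9)
  }
  # world mapping consistency after the round-trip
  f <- file.path(dir, "v.nii.gz")
  v2 <- read_volume(f)
  expect_equal(index_to_world(v2, c(3, 4, 5)), index_to_world(vol, c(3, 4, 5)),
               tolerance = 1e-5)
})

test_that("the CLI runs the pipeline and is deterministic", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "r1.json"); out2 <- file.path(dir, "r2.json")
  expect_equal(suppressMessages(
    cli_main(c("run-study", "--seed", "7", "--out", out1, "--log-level", "quiet"))), 0L)
  expect_equal(suppressMessages(
    cli_main(c("run-study", "--seed", "7", "--out", out2, "--log-level", "quiet"))), 0L)
  expect_identical(readLines(out1), readLines(out2))

  # unreachable plan: exit code 2 and a message naming the limit
  msgs <- character(0)
  status <- withCallingHandlers(
    cli_main(c("plan", "--entry", "0,0,0", "--target", "0,50,30",
               "--out", file.path(dir, "p.json"))),
    message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") })
  expect_equal(status, 2L)
  expect_true(any(grepl("cranial limit", msgs)))

  # evaluate subcommand prints the worked metric triple
  f <- file.path(dir, "eval.txt")
  expect_equal(suppressMessages(
    cli_main(c("evaluate", "--entry", "0,0,0", "--target", "0,0,100",
               "--tip", "2,0,100", "--out", f))), 0L)
  txt <- readLines(f)
  expect_match(txt[1], "1.1458")
  expect_match(txt[2], "2.0000")

  expect_equal(suppressMessages(cli_main(c("no-such-command"))), 2L)
})

test_that("the CLI chains simulate-phantom, detect and calibrate on disk", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "ph")
  expect_equal(suppressMessages(
    cli_main(c("simulate-phantom", "--out", prefix, "--dims", "128",
               "--log-level", "quiet"))), 0L)
  expect_true(file.exists(paste0(prefix, ".nii.gz")))
  cand_f <- file.path(dir, "cands.json")
  expect_equal(suppressMessages(
    cli_main(c("detect", "--volume", paste0(prefix, ".nii.gz"),
               "--out", cand_f, "--log-level", "quiet"))), 0L)
  expect_length(read_candidates(cand_f), 4)
  cal_f <- file.path(dir, "cal.json")
  expect_equal(suppressMessages(
    cli_main(c("calibrate", "--volume", paste0(prefix, ".nii.gz"),
               "--tool", paste0(prefix, "_tool.json"),
               "--out", cal_f, "--log-level", "quiet"))), 0L)
  cal <- read_calibration(cal_f)
  expect_lt(sqrt(sum(cal$tool_pose$translation^2)), 0.1)
})
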