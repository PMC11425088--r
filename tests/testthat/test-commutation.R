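arena10 <- arena_spec("circular", size_m = 0.345, px_per_m = 1000, fps = 10)
track <- arena_spec("linear", size_m = 1.2, px_per_m = 1000, fps = 10)

test_that("heading_vector normalizes and rejects coincident keypoints", {
  expect_equal(heading_vector(c(10, 0), c(0, 0)), c(1, 0))
  expect_equal(heading_vector(c(0, 5), c(0, 0)), c(0, 1))
  expect_equal(sqrt(sum(heading_vector(c(3, 7), c(-2, 1))^2)), 1)
  expect_error(heading_vector(c(3, 3), c(3, 3)), "degenerate")
})

test_that("signed_delta_deg follows the dot/cross convention with the +180 tie-break", {
  expect_equal(signed_delta_deg(c(1, 0), c(1, 0)), 0)
  expect_equal(signed_delta_deg(c(1, 0), c(0, 1)), 90)   # CW in y-down view
  expect_equal(signed_delta_deg(c(0, 1), c(1, 0)), -90)
  expect_equal(signed_delta_deg(c(1, 0), c(-1, 0)), 180)
  expect_equal(signed_delta_deg(c(0, -1), c(0, 1)), 180)
  expect_error(signed_delta_deg(c(2, 0), c(1, 0)), "unit")
})

test_that("signed_delta_deg matches the atan2 unwrapping oracle on random pairs", {
  v <- random_unit_vectors(2000, seed = 101)
  w <- random_unit_vectors(2000, seed = 202)
  for (i in seq_len(nrow(v))) {
    got <- signed_delta_deg(v[i, ], w[i, ])
    expect_equal(got, atan2_delta_oracle(v[i, ], w[i, ]), tolerance = 1e-9)
  }
})

test_that("the accumulator triggers at the threshold and conserves total rotation", {
  # constant heading: no commands ever
  s <- pirouette_stream(0, step_deg = 0)
  s <- pose_stream(0:49, head_x = 230, head_y = 200, tail_x = 170, tail_y = 200,
                   timestamp_s = (0:49) / 10)
  log <- run_closed_loop(s, arena10, controller_config(90, stride = 1))
  expect_equal(nrow(log$commands), 0)
  expect_equal(log$frames$twist_deg, rep(0, 50))

  # 720-deg CW pirouette, 2 deg per frame
  p <- pirouette_stream(720)
  l90 <- run_closed_loop(p, arena10, controller_config(90, stride = 1))
  expect_equal(sum(l90$commands$kind == "rotate_by"), 8)
  expect_equal(sum(l90$commands$rotate_deg) + l90$residual_deg, 720,
               tolerance = 1e-6)
  l225 <- run_closed_loop(p, arena10, controller_config(225, stride = 1))
  expect_equal(sum(l225$commands$kind == "rotate_by"), 3)
  expect_true(all(abs(l225$commands$rotate_deg) >= 225))
  expect_lt(abs(l225$residual_deg), 225)
  expect_equal(sum(l225$commands$rotate_deg) + l225$residual_deg, 720,
               tolerance = 1e-6)
})

test_that("rotation conservation holds on random walks with stride 1 and full confidence", {
  for (seed in c(21, 22, 23)) {
    tr <- generate_trajectory(arena10, duration_s = 60, turn_rate_sd = 120,
                              seed = seed)
    log <- run_closed_loop(tr$stream, arena10, controller_config(90, stride = 1))
    net <- tail(tr$truth$cumrot_deg, 1)
    expect_equal(sum(log$commands$rotate_deg, na.rm = TRUE) + log$residual_deg,
                 net, tolerance = 1e-6)
  }
})

test_that("stride and confidence gating skip frames without emitting commands", {
  p <- pirouette_stream(720)
  l5 <- run_closed_loop(p, arena10, controller_config(90, stride = 5))
  # every 5th frame processed: 10 deg per estimate, conservation still holds
  expect_equal(sum(l5$commands$rotate_deg) + l5$residual_deg, 720,
               tolerance = 1e-6)
  # gate everything: no commands, no accumulation
  pg <- p; pg$head_conf[] <- 0.5
  lg <- run_closed_loop(pg, arena10, controller_config(90, stride = 1))
  expect_equal(nrow(lg$commands), 0)
  expect_equal(lg$final_state$total_deg, 0)
})

test_that("raising the confidence gate never increases the number of processed frames", {
  tr <- generate_trajectory(arena10, duration_s = 40, seed = 31)
  s <- corrupt_poses(tr$stream, dropout_rate = 0.4, seed = 32)
  processed <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th) {
    st <- heading_state(); n <- 0L
    cfg <- controller_config(90, conf_threshold = th, stride = 1)
    for (i in seq_len(nrow(s))) {
      before <- st$last_accept_time_s
      up <- suppressWarnings(update_heading(st, s[i, ], cfg))  # gap warnings expected here
      st <- up$state
      if (!identical(before, st$last_accept_time_s)) n <- n + 1L
    }
    n
  }, 0L)
  expect_true(all(diff(processed) <= 0))
})

test_that("segment binning is half-open with an end clamp", {
  expect_equal(segment_index(0, track), 0L)
  expect_equal(segment_index(0.15 * 1000, track), 1L)   # boundary goes up
  expect_equal(segment_index(0.1499 * 1000, track), 0L)
  expect_equal(segment_index(1.2 * 1000, track), 7L)    # far-end clamp
  expect_error(segment_index(1.25 * 1000, track), "out-of-arena")
  expect_equal(segment_center_m(1), 0.225)
})

test_that("a monotone traverse emits 7 segment-center translations; oscillation emits one per crossing", {
  n <- 120
  xs <- seq(0, 1.2, length.out = n) * 1000
  s <- pose_stream(0:(n - 1), xs, 50, xs - 60, 50, timestamp_s = (0:(n - 1)) / 10)
  log <- run_closed_loop(s, track, controller_config(stride = 1))
  tcmd <- log$commands[log$commands$kind == "translate_to", ]
  expect_equal(nrow(tcmd), 7)
  expect_equal(tcmd$target_x_m, segment_center_m(1:7), tolerance = 1e-9)

  # oscillate across the 0.15 m boundary k times
  k <- 6
  xo <- rep(c(140, 160), k) # alternate segments 0 and 1
  so <- pose_stream(0:(2 * k - 1), xo, 50, xo - 60, 50)
  st <- heading_state(); cnt <- 0
  cfg <- controller_config(stride = 1)
  for (i in seq_len(nrow(so))) {
    up <- update_translation(st, so[i, ], track, cfg)
    st <- up$state
    if (up$command$kind == "translate_to") cnt <- cnt + 1
  }
  expect_equal(cnt, 2 * k - 1)  # every frame after the first changes segment
})

test_that("the stage simulator rate-limits motion, queues FIFO, and clamps at track ends", {
  cfg <- controller_config(rotation_speed_dps = 100, translation_speed_mps = 0.2)
  st <- stage_state()
  st <- step_stage(st, motor_command("rotate_by", rotate_deg = 90), dt_s = 0.5, cfg)
  expect_equal(st$angle_deg, 50)
  expect_true(st$busy)
  st <- step_stage(st, NULL, dt_s = 0.5, cfg)
  expect_equal(st$angle_deg, 90)
  expect_false(st$busy)
  # none command: state unchanged except time
  st2 <- step_stage(st, motor_command("none"), dt_s = 1, cfg)
  expect_equal(st2$angle_deg, st$angle_deg)
  expect_equal(st2$time_s, st$time_s + 1)
  # FIFO: two rotations queued back to back complete in order
  st3 <- stage_state()
  st3 <- step_stage(st3, motor_command("rotate_by", rotate_deg = 10), dt_s = 1e-6, cfg)
  st3 <- step_stage(st3, motor_command("rotate_by", rotate_deg = -5), dt_s = 0.1 - 1e-6, cfg)
  expect_equal(st3$angle_deg, 10 - 100 * (0.1 - 10 / 100), tolerance = 1e-6)
  # translation beyond the track end stops at the limit switch
  st4 <- stage_state(x_m = 1.1)
  st4 <- step_stage(st4, motor_command("translate_to", target_x_m = 5), dt_s = 10, cfg)
  expect_equal(st4$x_m, 1.2)
})

test_that("closed-loop twist stays bounded and the run log is deterministic", {
  p <- pirouette_stream(720)
  cfg <- controller_config(90, stride = 1, rotation_speed_dps = 1e6)
  l1 <- run_closed_loop(p, arena10, cfg)
  l2 <- run_closed_loop(p, arena10, cfg)
  expect_identical(l1, l2)
  expect_lt(max(abs(l1$frames$twist_deg)), 90 + 2 + 1e-9)
})

test_that("run logs serialize to JSON lines and a protocol-bearing command CSV", {
  p <- pirouette_stream(360)
  log <- run_closed_loop(p, arena10, controller_config(90, stride = 1))
  j <- withr::local_tempfile(fileext = ".jsonl")
  cc <- withr::local_tempfile(fileext = ".csv")
  write_run_log(log, j, cc)
  lines <- readLines(j)
  expect_equal(length(lines), nrow(log$frames))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("frame", "twist_deg", "commutator_angle_deg") %in% names(rec)))
  cmd <- read.csv(cc)
  expect_true(all(grepl("^R ", cmd$protocol[cmd$kind == "rotate_by"])))
})
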