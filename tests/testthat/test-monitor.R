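test_that("per-axis region bounds are strict, as printed", {
  ref <- c(500, 250)
  expect_true(cop_region_test(c(530, 250), ref, 40, "box")$inside)   # 460<530<540
  expect_false(cop_region_test(c(541, 250), ref, 40, "box")$inside)  # 540<541
  expect_false(cop_region_test(c(540, 250), ref, 40, "box")$inside)  # d = 1 exactly
  z <- cop_region_test(ref, ref, 40, "box")
  expect_true(z$inside); expect_equal(z$d, 0)
  expect_true(cop_region_test(cop_point(530, 250, 1),
                              cop_point(500, 250, 1), 40)$inside)
})

test_that("box mode matches a brute-force bound check; circle implies box", {
  set.seed(91)
  for (i in 1:300) {
    ref <- c(runif(1, 0, 1000), runif(1, 0, 500))
    cop <- ref + runif(2, -80, 80)
    a <- runif(1, 5, 60)
    box <- cop_region_test(cop, ref, a, "box")
    brute <- (ref[1] - a < cop[1]) && (cop[1] < ref[1] + a) &&
             (ref[2] - a < cop[2]) && (cop[2] < ref[2] + a)
    expect_identical(box$inside, brute)
    circ <- cop_region_test(cop, ref, a, "circle")
    if (circ$inside) expect_true(box$inside)
    expect_gte(circ$d, box$d)
  }
})

test_that("lean severity bands map displacement to feedback states", {
  expect_equal(as.character(lean_severity(c(0, 0.4, 0.5, 0.75, 0.8, 0.99, 1, 1.2))),
               c("balanced", "balanced", "slight", "slight", "severe",
                 "severe", "broken", "broken"))
  expect_true(is.ordered(lean_severity(0.3)))
})

test_that("a frame matching its calibration is good stance with no flags", {
  prof <- ideal_profile()
  a <- assess_frame(ideal_frame(), prof)
  expect_equal(a$state, "Ms")
  expect_length(a$flags, 0)
  expect_equal(as.character(a$lean_severity), "balanced")
  expect_lt(a$displacement_norm, 0.1)
})

test_that("a lateral lean beyond alpha flags the overall COP and points the right way", {
  prof <- ideal_profile()
  lean <- ideal_frame(lean_vector_mm = c(-60, 0))  # lean left, past alpha = 40
  a <- assess_frame(lean, prof)
  expect_equal(a$state, "Mp")
  expect_true("cop_overall" %in% a$flags)
  expect_lt(a$lean_direction[1], -0.9)
  expect_equal(as.character(a$lean_severity), "broken")
})

test_that("foot repositioning and orientation drift raise their flags", {
  prof <- ideal_profile()
  shifted <- ideal_frame(shift_right_mm = c(80, 0))
  expect_true("foot_position" %in% assess_frame(shifted, prof)$flags)

  twisted <- ideal_frame(toe_angle_left_deg = 40)  # 22 deg drift from 18
  expect_true("foot_orientation" %in% assess_frame(twisted, prof)$flags)

  empty <- filter_frame(synth_frame(stance_spec(body_mass_kg = 0))$frame)
  expect_error(assess_frame(empty, prof), "missing foot")
  a <- assess_frame(empty, prof, on_missing_foot = "flag")
  expect_equal(a$flags, "foot_position")
  expect_equal(a$state, "Mp")
})

test_that("enlarging alpha never turns good stance into poor", {
  frames <- list(ideal_frame(lean_vector_mm = c(25, 0)),
                 ideal_frame(lean_vector_mm = c(45, 10)),
                 ideal_frame(lean_vector_mm = c(0, -35)))
  fr_cal <- ideal_frame()
  for (mode in c("box", "circle")) {
    for (fr in frames) {
      for (a1 in c(20, 40, 60)) {
        s1 <- assess_frame(fr, calibrate(fr_cal, alpha_mm = a1),
                           monitor = monitor_params(alpha_mm = a1,
                                                    region_mode = mode))$state
        s2 <- assess_frame(fr, calibrate(fr_cal, alpha_mm = 2 * a1),
                           monitor = monitor_params(alpha_mm = 2 * a1,
                                                    region_mode = mode))$state
        if (s1 == "Ms") expect_equal(s2, "Ms")
      }
    }
  }
})

test_that("mirroring frame and profile swaps the left/right flags", {
  cfg <- default_cfg
  cal <- ideal_frame()
  lean <- ideal_frame(lean_vector_mm = c(-55, 0))
  a <- assess_frame(lean, calibrate(cal))
  am <- assess_frame(mirror_frame(lean, cfg), calibrate(mirror_frame(cal, cfg)))
  swap <- function(fl) {
    out <- fl
    out[fl == "cop_left"] <- "cop_right"
    out[fl == "cop_right"] <- "cop_left"
    out
  }
  expect_setequal(am$flags, swap(a$flags))
  expect_equal(am$displacement_norm, a$displacement_norm, tolerance = 1e-9)
  expect_equal(am$lean_direction[1], -a$lean_direction[1], tolerance = 1e-9)
})

test_that("the timer counts good frames and freezes at the break", {
  rec <- new_session(fps = 20)
  for (i in 1:600) rec <- session_step(rec, fake_assessment("Ms"))
  expect_equal(rec$good_duration_s, 30)
  expect_equal(rec$phase, "TRAINING")

  rec <- session_step(rec, fake_assessment("Mp"))
  expect_equal(rec$phase, "BROKEN")
  expect_equal(rec$good_duration_s, 30)
  expect_equal(rec$break_time_s, 30)
  expect_equal(rec$final_level, 3L)
  expect_equal(rec$final_group, "beginner")
  expect_equal(rec$events[[length(rec$events)]]$event, "break_notification")

  expect_warning(rec2 <- session_step(rec, fake_assessment("Ms")),
                 "already BROKEN")
  expect_equal(rec2$good_duration_s, rec$good_duration_s)
})

test_that("a poor first frame breaks immediately; debounce tolerates blips", {
  rec <- session_step(new_session(fps = 20), fake_assessment("Mp"))
  expect_equal(rec$phase, "BROKEN")
  expect_equal(rec$good_duration_s, 0)
  expect_equal(rec$break_time_s, 0)

  rec3 <- new_session(fps = 20, debounce = 3L)
  for (s in c("Ms", "Mp", "Mp", "Ms", "Mp", "Mp")) {
    rec3 <- session_step(rec3, fake_assessment(s))
  }
  expect_equal(rec3$phase, "TRAINING")
  rec3 <- session_step(rec3, fake_assessment("Mp"))
  expect_equal(rec3$phase, "BROKEN")
})

test_that("run_session replays a scripted stream deterministically", {
  cfg <- default_cfg
  prof <- ideal_profile()
  ss <- synth_session(stance_spec(noise_sd = 8),
                      session_script(break_at_s = 4.15, hold_s = 5, seed = 5),
                      cfg)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  r1 <- run_session(ss$frames, prof, log_path = p1)
  r2 <- run_session(ss$frames, prof, log_path = p2)
  expect_equal(glance(r1), glance(r2))
  expect_identical(readLines(p1), readLines(p2))

  expect_equal(r1$phase, "BROKEN")
  expect_lt(abs(r1$good_duration_s - ss$truth$expected_duration_s), 1 / 20 + 1e-9)
  expect_equal(nrow(tidy(r1)), r1$frames_seen)
})

test_that("a stream that never enters a valid stance aborts the session", {
  cfg <- default_cfg
  prof <- ideal_profile()
  bad <- replicate(5, synth_frame(stance_spec(lr_split = 0.75))$frame,
                   simplify = FALSE)
  rec <- run_session(bad, prof)
  expect_true(rec$aborted)
  expect_match(rec$abort_reason, "entry")
  expect_equal(rec$good_duration_s, 0)
})
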