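test_that("rendered frames scale with body mass and respect the sensor range", {
  cfg <- default_cfg
  expect_equal(total_pressure(synth_frame(stance_spec(body_mass_kg = 0))$frame),
               0)
  t40 <- total_pressure(synth_frame(stance_spec(body_mass_kg = 40))$frame)
  t80 <- total_pressure(synth_frame(stance_spec(body_mass_kg = 80))$frame)
  expect_lt(abs(t80 / t40 - 2), 0.02)   # proportional within quantisation

  fr <- synth_frame(stance_spec())$frame
  expect_true(all(fr >= 0) && all(fr <= cfg$max_raw))
  expect_lt(max(fr), 0.7 * cfg$max_raw)  # no saturation for an 80 kg subject
  expect_gt(max(fr), 0.5 * cfg$max_raw)
})

test_that("a symmetric stance puts the overall COP at the stance midpoint", {
  cfg <- default_cfg
  out <- synth_frame(stance_spec())
  cop <- compute_cop(filter_frame(out$frame), cfg)
  expect_lt(abs(cop$x - 500), 0.5 * cfg$pitch_x)
  expect_lt(abs(cop$y - 250), 0.5 * cfg$pitch_y)
  expect_equal(out$truth$cop_o$x, 500)
})

test_that("the imposed lean moves the true COP by the lean vector", {
  out0 <- synth_frame(stance_spec())
  out <- synth_frame(stance_spec(lean_vector_mm = c(30, -20)))
  expect_equal(out$truth$cop_o$x - out0$truth$cop_o$x, 30, tolerance = 1e-9)
  expect_equal(out$truth$cop_o$y - out0$truth$cop_o$y, -20, tolerance = 1e-9)
  # and the rendered frame follows the model
  cop <- compute_cop(filter_frame(out$frame), default_cfg)
  expect_lt(abs(cop$x - out$truth$cop_o$x), 6)
  expect_lt(abs(cop$y - out$truth$cop_o$y), 6)
})

test_that("generation is deterministic per seed and leaves the RNG alone", {
  s <- stance_spec(noise_sd = 15, seed = 99)
  f1 <- synth_frame(s)$frame
  set.seed(1); before <- runif(1)
  f2 <- synth_frame(s)$frame
  expect_identical(unclass(f1)[, ], unclass(f2)[, ])

  set.seed(1)
  synth_frame(s)
  expect_equal(runif(1), before)  # caller RNG untouched

  sc <- session_script(break_at_s = 2, hold_s = 2, seed = 3)
  s1 <- synth_session(stance_spec(noise_sd = 10), sc)
  s2 <- synth_session(stance_spec(noise_sd = 10), sc)
  expect_identical(lapply(s1$frames, unclass), lapply(s2$frames, unclass))
})

test_that("stances that do not fit the mat are rejected", {
  expect_error(synth_frame(stance_spec(stance_width_mm = 950)), "off-mat")
  expect_error(synth_frame(stance_spec(center_y_mm = 60)), "off-mat")
  expect_error(stance_spec(lr_split = 1.2), "lr_split")
})

test_that("estimators recover the generator's parameters across seeded stances", {
  cfg <- default_cfg
  set.seed(123)
  n_ok <- 0L
  for (i in 1:25) {
    spec <- stance_spec(
      body_mass_kg = runif(1, 55, 100),
      stance_width_mm = runif(1, 410, 520),
      toe_angle_left_deg = runif(1, 5, 40),
      toe_angle_right_deg = runif(1, 5, 40),
      lr_split = runif(1, 0.45, 0.55),
      fore_frac_left = runif(1, 0.35, 0.65),
      fore_frac_right = runif(1, 0.35, 0.65),
      noise_sd = runif(1, 0, 0.02 * cfg$max_raw),
      seed = 1000 + i
    )
    out <- synth_frame(spec)
    halves <- split_left_right(filter_frame(out$frame), cfg)
    l <- detect_foot(halves$left, cfg)
    r <- detect_foot(halves$right, cfg)
    expect_lt(abs(l$toe_angle_deg - spec$toe_angle_left_deg), 2)
    expect_lt(abs(r$toe_angle_deg - spec$toe_angle_right_deg), 2)
    width <- stance_metrics(l, r, cfg)$stance_width_mm
    expect_lt(abs(width - out$truth$stance_width_mm), cfg$pitch_x)
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 25L)
})

test_that("imposed leans past alpha are flagged with a faithful direction", {
  cfg <- default_cfg
  prof <- ideal_profile()
  alpha <- prof$alpha_mm
  set.seed(321)
  hits <- 0L; n <- 40L
  for (i in 1:n) {
    ang <- runif(1, 0, 2 * pi)
    mag <- runif(1, 1.2, 1.5) * alpha
    lean <- mag * c(cos(ang), sin(ang))
    fr <- ideal_frame(lean_vector_mm = lean, noise_sd = 10,
                      seed = 5000 + i)
    a <- assess_frame(fr, prof)
    dir_err <- acos(max(-1, min(1, sum(a$lean_direction * lean / mag)))) * 180 / pi
    if (a$state == "Mp" && dir_err < 30) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("scripted breaks are detected at the scripted time with the right label", {
  cfg <- default_cfg
  prof <- ideal_profile()
  for (mode in c("lean_out", "foot_shift", "rise")) {
    ss <- synth_session(stance_spec(noise_sd = 10),
                        session_script(break_mode = mode, break_at_s = 3.4,
                                       hold_s = 4, seed = 17), cfg)
    rec <- run_session(ss$frames, prof)
    expect_equal(rec$phase, "BROKEN")
    expect_lt(abs(rec$good_duration_s - ss$truth$expected_duration_s),
              2 / 20 + 1e-9)
    expect_true(ss$truth$expected_flag %in% rec$terminal_flags)
  }
})

test_that("cohort durations carry the condition effect and are exchangeable under the null", {
  coh <- synth_condition_cohort(n_per_condition = 14, seed = 42)
  expect_equal(nrow(coh), 42L)
  expect_setequal(unique(coh$condition), c("NFB", "CFB", "GFB"))
  expect_equal(coh$final_level, level_for_duration(coh$duration_s))

  # strong default effect: GFB median beats NFB in almost every replicate
  wins <- sum(vapply(1:50, function(r) {
    d <- synth_condition_cohort(seed = r)
    median(d$duration_s[d$condition == "GFB"]) >
      median(d$duration_s[d$condition == "NFB"])
  }, TRUE))
  expect_gte(wins / 50, 0.95)

  # null: equal medians give p-values that are not systematically small
  ps <- vapply(1:30, function(r) {
    d <- synth_condition_cohort(n_per_condition = 6,
                                medians = c(NFB = 50, GFB = 50),
                                seed = 100 + r)
    mann_whitney_u(d$duration_s[d$condition == "GFB"],
                   d$duration_s[d$condition == "NFB"])$p_two_sided
  }, 0)
  expect_gt(mean(ps), 0.3)
})
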