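test_that("detected centroid matches the simulator's ground truth", {
  cfg <- default_cfg
  out <- synth_frame(stance_spec(lr_split = 0.55, fore_frac_left = 0.6))
  halves <- split_left_right(filter_frame(out$frame), cfg)
  l <- detect_foot(halves$left, cfg)
  r <- detect_foot(halves$right, cfg)
  tol <- 0.5 * max(cfg$pitch_x, cfg$pitch_y)
  expect_lt(abs(l$centroid$x - out$truth$cop_l$x), tol)
  expect_lt(abs(l$centroid$y - out$truth$cop_l$y), tol)
  expect_lt(abs(r$centroid$x - out$truth$cop_r$x), tol)

  # centroid is exactly the half-frame COP
  expect_equal(l$centroid, compute_cop(halves$left, cfg))

  expect_error(detect_foot(split_left_right(
    filter_frame(synth_frame(stance_spec(body_mass_kg = 0))$frame), cfg)$left,
    cfg), "empty half-frame")
})

test_that("orientation: aligned, rotated and inward-rotated blobs", {
  cfg <- default_cfg
  # hand-built axis-aligned elongated blob (long axis anterior)
  m <- matrix(0L, cfg$rows, cfg$cols)
  m[6:17, 10:12] <- 500L
  half <- split_left_right(pressure_frame(m, cfg), cfg)$left
  expect_lt(abs(foot_orientation(half, cfg)), 0.5)

  # simulator feet rotated 20 degrees outward
  fr <- ideal_frame(toe_angle_left_deg = 20, toe_angle_right_deg = 20)
  halves <- split_left_right(fr, cfg)
  expect_lt(abs(foot_orientation(halves$left, cfg) - 20), 1)
  expect_lt(abs(foot_orientation(halves$right, cfg) - 20), 1)

  # inward rotation gives a negative outward angle
  fr_in <- ideal_frame(toe_angle_left_deg = -10, toe_angle_right_deg = -10)
  halves_in <- split_left_right(fr_in, cfg)
  expect_lt(foot_orientation(halves_in$left, cfg), -5)
  expect_lt(foot_orientation(halves_in$right, cfg), -5)
})

test_that("orientation errors on degenerate blobs", {
  cfg <- default_cfg
  m <- matrix(0L, cfg$rows, cfg$cols)
  m[5, 5] <- 100L; m[6, 5] <- 100L
  expect_error(foot_orientation(split_left_right(pressure_frame(m, cfg),
                                                 cfg)$left, cfg),
               "degenerate blob")
  m[7, 5] <- 100L  # three collinear cells
  expect_error(foot_orientation(split_left_right(pressure_frame(m, cfg),
                                                 cfg)$left, cfg),
               "degenerate blob")
})

test_that("orientation is rotation-consistent within the working band", {
  cfg <- default_cfg
  base <- foot_orientation(split_left_right(ideal_frame(), cfg)$left, cfg)
  for (delta in c(-20, -10, 10, 25)) {
    est <- foot_orientation(split_left_right(
      ideal_frame(toe_angle_left_deg = 18 + delta,
                  toe_angle_right_deg = 18 + delta), cfg)$left, cfg)
    expect_lt(abs((est - base) - delta), 1)
  }
})

test_that("translation moves the centroid and preserves angle and split", {
  cfg <- default_cfg
  shift <- c(2 * cfg$pitch_x, -1 * cfg$pitch_y)
  a <- detect_foot(split_left_right(ideal_frame(fore_frac_left = 0.6),
                                    cfg)$left, cfg)
  b <- detect_foot(split_left_right(
    ideal_frame(fore_frac_left = 0.6, shift_left_mm = shift), cfg)$left, cfg)
  expect_lt(abs((b$centroid$x - a$centroid$x) - shift[1]), 0.5 * cfg$pitch_x)
  expect_lt(abs((b$centroid$y - a$centroid$y) - shift[2]), 0.5 * cfg$pitch_y)
  expect_lt(abs(b$toe_angle_deg - a$toe_angle_deg), 0.5)
  expect_lt(abs(b$fore_load_frac - a$fore_load_frac), 0.02)
})

test_that("heel/forefoot split recovers the loading and sums to one", {
  cfg <- default_cfg
  for (f in c(0.35, 0.5, 0.7)) {
    out <- synth_frame(stance_spec(fore_frac_left = f, fore_frac_right = f))
    halves <- split_left_right(filter_frame(out$frame), cfg)
    l <- detect_foot(halves$left, cfg)
    expect_lt(abs(l$fore_load_frac - f), 0.05)
    expect_equal(l$heel_load_frac + l$fore_load_frac, 1, tolerance = 1e-9)
    hf <- heel_fore_split(l, halves$left, cfg)
    expect_equal(unname(hf[["fore"]]), l$fore_load_frac)
  }
  # strongly heel-loaded foot
  outh <- synth_frame(stance_spec(fore_frac_left = 0.2, fore_frac_right = 0.2))
  lh <- detect_foot(split_left_right(filter_frame(outh$frame), cfg)$left, cfg)
  # the centroid-boundary estimator compresses extreme splits, so assert
  # clear heel dominance rather than the nominal 0.8
  expect_gt(lh$heel_load_frac, 0.6)
})

test_that("stance metrics: width, centre-line offsets, balance", {
  cfg <- default_cfg
  fr <- ideal_frame(stance_width_mm = 400)
  halves <- split_left_right(fr, cfg)
  l <- detect_foot(halves$left, cfg); r <- detect_foot(halves$right, cfg)
  m <- stance_metrics(l, r, cfg)
  expect_lt(abs(m$stance_width_mm - 400), cfg$pitch_x)
  expect_lt(m$centerline_offset_left_mm, 0.5 * cfg$pitch_y)
  expect_lt(m$centerline_offset_right_mm, 0.5 * cfg$pitch_y)
  expect_lt(m$lr_balance, 0.01)

  # 60/40 loading: |Pl - Pr| / (Pl + Pr) = 0.20
  out <- synth_frame(stance_spec(lr_split = 0.6))
  h2 <- split_left_right(filter_frame(out$frame), cfg)
  m2 <- stance_metrics(detect_foot(h2$left, cfg), detect_foot(h2$right, cfg),
                       cfg)
  expect_lt(abs(m2$lr_balance - 0.2), 0.02)
})

test_that("left/right balance is invariant to uniform pressure scaling", {
  cfg <- default_cfg
  fr <- filter_frame(synth_frame(stance_spec(body_mass_kg = 35,
                                             lr_split = 0.58))$frame)
  fr2 <- pressure_frame(unclass(fr) * 2L, cfg)
  bal <- function(f) {
    h <- split_left_right(f, cfg)
    stance_metrics(detect_foot(h$left, cfg), detect_foot(h$right, cfg),
                   cfg)$lr_balance
  }
  expect_equal(bal(fr2), bal(fr), tolerance = 1e-12)
})

test_that("mirror-image halves give mirrored centroids and matching outward angles", {
  cfg <- default_cfg
  fr <- ideal_frame(toe_angle_left_deg = 22, toe_angle_right_deg = 22)
  mfr <- mirror_frame(fr, cfg)
  l <- detect_foot(split_left_right(fr, cfg)$left, cfg)
  rm <- detect_foot(split_left_right(mfr, cfg)$right, cfg)
  expect_equal(rm$centroid$x, cfg$length_mm - l$centroid$x, tolerance = 1e-9)
  expect_equal(rm$toe_angle_deg, l$toe_angle_deg, tolerance = 1e-9)
})
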