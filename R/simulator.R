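# Foot pressure model: two anisotropic Gaussian lobes per foot, centred on
# the foot axis at u = -80 mm (heel) and u = +80 mm (forefoot). Sigmas in mm,
# (along-axis, across-axis). The heel lobe is tighter, reproducing the
# heel/sole hotspot structure of real wide-stance heat maps.
LOBE_U <- c(heel = -80, fore = 80)
LOBE_SIGMA <- list(heel = c(25, 22), fore = c(30, 30))

# Raw units per kg, chosen so that an 80 kg balanced stance peaks near 60%
# of full scale (avoids saturation while using the sensor's range).
raw_per_kg <- function(config) {
  pitch_area <- config$pitch_x * config$pitch_y
  peak_density <- max(vapply(LOBE_SIGMA,
                             function(s) 1 / (2 * pi * s[1] * s[2]), 0))
  0.6 * config$max_raw / (80 * 0.25 * pitch_area * peak_density)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a simulated wide stance
#'
#' Parameters of one synthetic two-foot stance on the mat. The defaults
#' describe an ideal wide horse stance for an 80 kg adult: feet 450 mm
#' apart on the mat's centre-line, 18 degrees of toe-out, load split evenly
#' between feet and between heel and forefoot, no lean and no sensor noise.
#'
#' A lean is imposed as a weight redistribution, the way a human leans
#' without moving the feet: the `x` component shifts load between the feet
#' and the `y` component shifts each foot's heel/forefoot split, so the
#' overall COP moves by `lean_vector_mm` while the feet stay put.
#' `shift_left_mm` / `shift_right_mm` translate a whole foot instead
#' (an incorrect foot repositioning).
#'
#' @param body_mass_kg Body mass; total raw pressure is proportional to it.
#' @param stance_width_mm Distance between the two foot centres (mm).
#' @param center_x_mm,center_y_mm Stance centre on the mat; defaults to the
#'   mat centre of the default [sensor_config()].
#' @param toe_angle_left_deg,toe_angle_right_deg Outward toe rotation per
#'   foot (degrees).
#' @param lr_split Fraction of load on the left foot, in (0, 1).
#' @param fore_frac_left,fore_frac_right Forefoot load fraction per foot.
#' @param lean_vector_mm Length-2 COP offset to impose, mm `(x, y)`.
#' @param shift_left_mm,shift_right_mm Length-2 rigid translation of each
#'   foot, mm.
#' @param noise_sd Standard deviation of additive sensor noise (raw units);
#'   noise is truncated so cells stay non-negative.
#' @param seed Optional RNG seed for the noise; the caller's RNG state is
#'   left untouched.
#' @return A `stance_spec` list.
#' @export
stance_spec <- function(body_mass_kg = 80,
                        stance_width_mm = 450,
                        center_x_mm = 500, center_y_mm = 250,
                        toe_angle_left_deg = 18, toe_angle_right_deg = 18,
                        lr_split = 0.5,
                        fore_frac_left = 0.5, fore_frac_right = 0.5,
                        lean_vector_mm = c(0, 0),
                        shift_left_mm = c(0, 0), shift_right_mm = c(0, 0),
                        noise_sd = 0, seed = NULL) {
  stopifnot(body_mass_kg >= 0, stance_width_mm > 0,
            lr_split > 0, lr_split < 1,
            fore_frac_left > 0, fore_frac_left < 1,
            fore_frac_right > 0, fore_frac_right < 1,
            length(lean_vector_mm) == 2L, noise_sd >= 0)
  structure(
    list(body_mass_kg = body_mass_kg, stance_width_mm = stance_width_mm,
         center_x_mm = center_x_mm, center_y_mm = center_y_mm,
         toe_angle_left_deg = toe_angle_left_deg,
         toe_angle_right_deg = toe_angle_right_deg,
         lr_split = lr_split,
         fore_frac_left = fore_frac_left, fore_frac_right = fore_frac_right,
         lean_vector_mm = lean_vector_mm,
         shift_left_mm = shift_left_mm, shift_right_mm = shift_right_mm,
         noise_sd = noise_sd, seed = seed),
    class = "stance_spec"
  )
}

# Lobe centres, weights and shape parameters for a stance, in mat coords.
# The lean is imposed exactly: the per-foot forefoot fractions (a common
# anterior COP shift g) and the left-load fraction p are solved jointly so
# the overall COP lands at (no-lean COP) + lean_vector_mm, accounting for
# the x/y coupling that toe-out introduces.
stance_lobes <- function(spec, config) {
  T_raw <- spec$body_mass_kg * raw_per_kg(config)
  w <- spec$stance_width_mm
  lean <- spec$lean_vector_mm
  sep <- LOBE_U[["fore"]] - LOBE_U[["heel"]]

  feet <- list(
    left = list(center = c(spec$center_x_mm - w / 2, spec$center_y_mm) +
                  spec$shift_left_mm,
                theta = spec$toe_angle_left_deg * pi / 180,
                outward = -1, fore0 = spec$fore_frac_left),
    right = list(center = c(spec$center_x_mm + w / 2, spec$center_y_mm) +
                  spec$shift_right_mm,
                 theta = spec$toe_angle_right_deg * pi / 180,
                 outward = 1, fore0 = spec$fore_frac_right)
  )
  for (side in names(feet)) {
    f <- feet[[side]]
    feet[[side]]$axis <- c(f$outward * sin(f$theta), cos(f$theta))
    # foot COP at forefoot fraction fr sits (fr - 0.5) * sep along the axis
    feet[[side]]$cop0 <- f$center +
      feet[[side]]$axis * (f$fore0 - 0.5) * sep
  }
  p0 <- spec$lr_split
  target <- p0 * feet$left$cop0 + (1 - p0) * feet$right$cop0 + lean

  # fixed-point solve for (p, g); exact for zero lean, converges in a few
  # iterations otherwise
  p <- p0; g <- lean[2]
  for (it in 1:40) {
    cl <- feet$left$cop0 + feet$left$axis * g / cos(feet$left$theta)
    cr <- feet$right$cop0 + feet$right$axis * g / cos(feet$right$theta)
    p_new <- if (abs(cr[1] - cl[1]) < 1e-9) p else
      (cr[1] - target[1]) / (cr[1] - cl[1])
    g_new <- g + target[2] - (p_new * cl[2] + (1 - p_new) * cr[2])
    if (abs(p_new - p) < 1e-12 && abs(g_new - g) < 1e-12) break
    p <- p_new; g <- g_new
  }
  if (p <= 0.01 || p >= 0.99) {
    stop("imposed lateral lean exceeds the stance's load range", call. = FALSE)
  }

  lobes <- list()
  for (side in names(feet)) {
    f <- feet[[side]]
    share <- if (side == "left") p else 1 - p
    fore_eff <- f$fore0 + g / (sep * cos(f$theta))
    if (fore_eff <= 0.01 || fore_eff >= 0.99) {
      stop("imposed anterior/posterior lean exceeds the foot's load range",
           call. = FALSE)
    }
    for (lobe in c("heel", "fore")) {
      wt <- T_raw * share * if (lobe == "fore") fore_eff else 1 - fore_eff
      lobes[[paste(side, lobe, sep = "_")]] <- list(
        side = side, lobe = lobe,
        center = f$center + f$axis * LOBE_U[[lobe]],
        axis = f$axis, perp = c(f$axis[2], -f$axis[1]),
        sigma = LOBE_SIGMA[[lobe]],
        weight = wt, fore_eff = fore_eff, share = share
      )
    }
  }
  lobes
}

#' Render a synthetic pressure frame
#'
#' Renders the stance described by a [stance_spec()] onto the sensor grid:
#' each foot is a pair of anisotropic Gaussian pressure lobes (heel and
#' forefoot) rotated by the foot's toe angle; total raw pressure is
#' proportional to body mass; optional truncated-Gaussian sensor noise is
#' added; values are quantised to the sensor bit depth. Alongside the frame
#' the continuous-model ground truth is returned, for use as labels in
#' estimator-recovery tests.
#'
#' @param spec A [stance_spec()].
#' @param config A [sensor_config()].
#' @param timestamp_ms Frame timestamp.
#' @return List with `frame` (a raw [pressure_frame()]) and `truth`, a list
#'   carrying the continuous-model `cop_o`, `cop_l`, `cop_r` (cop_points),
#'   `toe_angle_left_deg`, `toe_angle_right_deg`, effective
#'   `fore_frac_left`, `fore_frac_right`, `lr_split` (left-load fraction
#'   after lean), `stance_width_mm` (distance between the per-foot COPs)
#'   and `lr_balance`.
#' @examples
#' out <- synth_frame(stance_spec(seed = 1, noise_sd = 10))
#' out$truth$cop_o
#' @export
synth_frame <- function(spec, config = sensor_config(), timestamp_ms = 0) {
  if (spec$body_mass_kg == 0) {
    fr <- pressure_frame(matrix(0L, config$rows, config$cols), config,
                         timestamp_ms = timestamp_ms)
    return(list(frame = fr, truth = NULL))
  }
  lobes <- stance_lobes(spec, config)

  margin <- function(l) 2.5 * max(l$sigma)
  for (l in lobes) {
    if (l$center[1] < margin(l) || l$center[1] > config$length_mm - margin(l) ||
        l$center[2] < margin(l) || l$center[2] > config$width_mm - margin(l)) {
      stop("stance off-mat: a pressure lobe falls outside the sensing area",
           call. = FALSE)
    }
  }

  grid <- cell_centers(pressure_frame(matrix(0L, config$rows, config$cols),
                                      config), config)
  pitch_area <- config$pitch_x * config$pitch_y
  vals <- numeric(config$rows * config$cols)
  for (l in lobes) {
    dx <- grid$x - l$center[1]
    dy <- grid$y - l$center[2]
    a <- (dx * l$axis[1] + dy * l$axis[2]) / l$sigma[1]
    b <- (dx * l$perp[1] + dy * l$perp[2]) / l$sigma[2]
    amp <- l$weight * pitch_area / (2 * pi * l$sigma[1] * l$sigma[2])
    vals <- vals + amp * exp(-0.5 * (a^2 + b^2))
  }
  if (spec$noise_sd > 0) {
    vals <- with_seed(spec$seed,
                      pmax(vals + rnorm(length(vals), 0, spec$noise_sd), 0))
  }
  vals <- pmin(pmax(round(vals), 0), config$max_raw)
  fr <- pressure_frame(matrix(vals, config$rows, config$cols), config,
                       timestamp_ms = timestamp_ms)

  wsum <- function(ls, i) sum(vapply(ls, function(l) l$weight * l$center[i], 0)) /
    sum(vapply(ls, function(l) l$weight, 0))
  lw <- lobes[vapply(lobes, function(l) l$side == "left", TRUE)]
  rw <- lobes[vapply(lobes, function(l) l$side == "right", TRUE)]
  tot <- function(ls) sum(vapply(ls, function(l) l$weight, 0))
  cop_l <- cop_point(wsum(lw, 1), wsum(lw, 2), tot(lw))
  cop_r <- cop_point(wsum(rw, 1), wsum(rw, 2), tot(rw))
  cop_o <- cop_point(wsum(lobes, 1), wsum(lobes, 2), tot(lobes))
  p_left <- tot(lw) / tot(lobes)

  list(
    frame = fr,
    truth = list(
      cop_o = cop_o, cop_l = cop_l, cop_r = cop_r,
      toe_angle_left_deg = spec$toe_angle_left_deg,
      toe_angle_right_deg = spec$toe_angle_right_deg,
      fore_frac_left = lw[["left_fore"]]$fore_eff,
      fore_frac_right = rw[["right_fore"]]$fore_eff,
      lr_split = p_left,
      lr_balance = abs(2 * p_left - 1),
      stance_width_mm = sqrt((cop_l$x - cop_r$x)^2 + (cop_l$y - cop_r$y)^2),
      lean_vector_mm = spec$lean_vector_mm
    )
  )
}

#' Script a simulated training session
#'
#' Describes a session stream: the practitioner holds the stance with a
#' bounded mean-reverting postural sway until `break_at_s`, then breaks it
#' in one of three ways mirroring how real stances end: `lean_out` (a
#' lateral weight shift past the valid COP region), `foot_shift` (one foot
#' moved to an incorrect position) or `rise` (standing up, unloading the
#' mat).
#'
#' @param fps Frame rate (frames per second).
#' @param hold_s Intended hold; frames are generated up to the break plus a
#'   short tail.
#' @param sway_amplitude_mm Bound on the sway of the overall COP (mm).
#' @param sway_timescale_s Mean-reversion timescale of the sway (s).
#' @param break_mode One of `"lean_out"`, `"foot_shift"`, `"rise"`.
#' @param break_at_s Scripted break time (s); must not exceed `hold_s`.
#' @param break_magnitude_mm Size of the break excursion (lean or foot
#'   shift), mm.
#' @param tail_frames Frames generated after the break.
#' @param seed RNG seed making the stream reproducible.
#' @return A `session_script` list.
#' @export
session_script <- function(fps = 20, hold_s = 30,
                           sway_amplitude_mm = 8, sway_timescale_s = 1,
                           break_mode = c("lean_out", "foot_shift", "rise"),
                           break_at_s = hold_s, break_magnitude_mm = 80,
                           tail_frames = 12L, seed = NULL) {
  break_mode <- match.arg(break_mode)
  stopifnot(fps > 0, break_at_s >= 0, break_at_s <= hold_s,
            sway_amplitude_mm >= 0, sway_timescale_s > 0,
            break_magnitude_mm > 0, tail_frames >= 1L)
  structure(
    list(fps = fps, hold_s = hold_s,
         sway_amplitude_mm = sway_amplitude_mm,
         sway_timescale_s = sway_timescale_s,
         break_mode = break_mode, break_at_s = break_at_s,
         break_magnitude_mm = break_magnitude_mm,
         tail_frames = as.integer(tail_frames), seed = seed),
    class = "session_script"
  )
}

#' Generate a scripted session frame stream
#'
#' Produces the stream of raw frames described by a [session_script()]
#' applied to a base [stance_spec()]. Before the break the overall COP
#' follows a discrete mean-reverting (Ornstein-Uhlenbeck-like) random walk
#' bounded by `sway_amplitude_mm`, realised as a weight-redistribution lean;
#' from `break_at_s` on, the break trajectory is applied. The stream is
#' deterministic for a given seed.
#'
#' @param stance Base [stance_spec()] (held posture).
#' @param script A [session_script()].
#' @param config A [sensor_config()].
#' @return List with `frames` (list of raw [pressure_frame()]s, frame `i`
#'   stamped at `(i - 1) / fps` seconds) and `truth` (list with
#'   `break_mode`, `break_at_s`, `break_frame` — 1-based index of the first
#'   broken frame — `expected_duration_s` and `expected_flag`).
#' @export
synth_session <- function(stance, script, config = sensor_config()) {
  fps <- script$fps
  k <- ceiling(script$break_at_s * fps - 1e-9)   # frames held (index 0..k-1)
  n <- k + script$tail_frames
  rho <- exp(-1 / (fps * script$sway_timescale_s))
  sd_stat <- script$sway_amplitude_mm / 3
  sd_step <- sd_stat * sqrt(1 - rho^2)

  with_seed(script$seed, {
    break_sign <- sample(c(-1, 1), 1L)
    sway <- c(0, 0)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      t_s <- (i - 1) / fps
      if (script$sway_amplitude_mm > 0) {
        sway <- sway * rho + rnorm(2L, 0, sd_step)
        nrm <- sqrt(sum(sway^2))
        if (nrm > script$sway_amplitude_mm) {
          sway <- sway * script$sway_amplitude_mm / nrm
        }
      }
      spec_i <- stance
      spec_i$seed <- NULL
      spec_i$lean_vector_mm <- stance$lean_vector_mm + sway
      if (t_s >= script$break_at_s - 1e-9) {
        spec_i <- switch(script$break_mode,
          lean_out = {
            spec_i$lean_vector_mm <- spec_i$lean_vector_mm +
              c(break_sign * script$break_magnitude_mm, 0)
            spec_i
          },
          foot_shift = {
            spec_i$shift_right_mm <- stance$shift_right_mm +
              c(script$break_magnitude_mm, 0)
            spec_i
          },
          rise = {
            spec_i$body_mass_kg <- stance$body_mass_kg * 0.01
            spec_i
          })
      }
      frames[[i]] <- synth_frame(spec_i, config,
                                 timestamp_ms = t_s * 1000)$frame
    }
    list(
      frames = frames,
      truth = list(
        break_mode = script$break_mode,
        break_at_s = script$break_at_s,
        break_frame = k + 1L,
        expected_duration_s = k / fps,
        expected_flag = switch(script$break_mode,
                               lean_out = "cop_overall",
                               foot_shift = "foot_position",
                               rise = "foot_position")
      )
    )
  })
}

#' Simulate a multi-condition training cohort
#'
#' Draws per-participant held durations for the three feedback conditions
#' of a balance-training experiment — no feedback (`NFB`), clock/stopwatch
#' feedback (`CFB`) and full game feedback (`GFB`) — from log-normal
#' distributions whose medians encode the feedback effect
#' (`GFB > CFB > NFB` by default). With `n_per_condition = 14` this mirrors
#' the design of a 14-participant study at simulation scale.
#'
#' @param n_per_condition Participants per condition (>= 2).
#' @param medians Named condition medians in seconds; equal medians give
#'   exchangeable (null) conditions.
#' @param sdlog Log-scale standard deviation of the duration distribution.
#' @param seed RNG seed.
#' @return Tibble with `participant_id`, `condition`, `duration_s`,
#'   `final_level`, `group`.
#' @export
synth_condition_cohort <- function(n_per_condition = 14,
                                   medians = c(NFB = 40, CFB = 55, GFB = 80),
                                   sdlog = 0.35, seed = NULL) {
  stopifnot(n_per_condition >= 2, all(medians > 0), sdlog >= 0,
            !is.null(names(medians)))
  with_seed(seed, {
    purrr::map_dfr(names(medians), function(cond) {
      dur <- stats::rlnorm(n_per_condition, meanlog = log(medians[[cond]]),
                           sdlog = sdlog)
      lvl <- level_for_duration(dur)
      tibble::tibble(
        participant_id = sprintf("%s-%02d", cond, seq_len(n_per_condition)),
        condition = cond,
        duration_s = dur,
        final_level = lvl,
        group = group_for_level(lvl)
      )
    })
  })
}
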