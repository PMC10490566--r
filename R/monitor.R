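#' Test a COP against its calibrated valid region
#'
#' The stance is considered held while each real-time COP stays within a
#' radius `alpha_mm` of its calibrated reference. Two region shapes are
#' supported. `"box"` applies strict per-axis bounds
#' (`ref_x - alpha < x < ref_x + alpha` and likewise in `y`) with the
#' normalised displacement `d = max(|dx|, |dy|) / alpha`; `"circle"` uses
#' the Euclidean distance, `d = ||delta|| / alpha`. In both modes the point
#' is inside iff `d < 1` (a displacement of exactly `alpha` is outside).
#' The circular region is inscribed in the box, so circle-inside implies
#' box-inside at equal `alpha_mm`.
#'
#' @param cop_t Real-time COP: a `cop_point` or an `(x, y)` vector in mm.
#' @param cop_ref Calibrated reference COP, same forms.
#' @param alpha_mm Region radius in mm (> 0).
#' @param mode `"box"` (default) or `"circle"`.
#' @return List with `inside` (logical) and `d` (normalised displacement).
#' @examples
#' cop_region_test(c(530, 250), c(500, 250), alpha_mm = 40)$inside  # TRUE
#' cop_region_test(c(541, 250), c(500, 250), alpha_mm = 40)$inside  # FALSE
#' @export
cop_region_test <- function(cop_t, cop_ref, alpha_mm,
                            mode = c("box", "circle")) {
  mode <- match.arg(mode)
  stopifnot(alpha_mm > 0)
  xy <- function(p) if (inherits(p, "cop_point")) c(p$x, p$y) else p[1:2]
  delta <- xy(cop_t) - xy(cop_ref)
  d <- if (mode == "box") max(abs(delta)) / alpha_mm
       else sqrt(sum(delta^2)) / alpha_mm
  list(inside = d < 1, d = d)
}

#' Lean-severity feedback state
#'
#' Maps the normalised COP displacement `d` onto the four in-game feedback
#' states: `balanced` (platform grey), `slight` (yellow), `severe` (red)
#' and `broken` (the avatar falls; the stance is lost). Band edges default
#' to 0.4 / 0.75 / 1 of the region radius and are configurable via
#' [monitor_params()].
#'
#' @param d Normalised displacement(s), `>= 0`.
#' @param bands Increasing band edges, see [monitor_params()].
#' @return Factor with levels `balanced < slight < severe < broken`.
#' @export
lean_severity <- function(d, bands = monitor_params()$lean_bands) {
  stopifnot(all(d >= 0, na.rm = TRUE), length(bands) == 3L)
  lv <- c("balanced", "slight", "severe", "broken")
  out <- ifelse(d <= bands[1], "balanced",
         ifelse(d <= bands[2], "slight",
         ifelse(d < bands[3], "severe", "broken")))
  factor(out, levels = lv, ordered = TRUE)
}

#' Assess one training frame against the calibration profile
#'
#' Classifies a frame as good (`Ms`) or poor (`Mp`) stance. The three COPs
#' (overall, left, right) are tested against their calibrated references
#' with [cop_region_test()]; a virtual flag is raised for any COP that
#' leaves its region. Additional flags: `foot_position` when a foot
#' centroid drifts more than `pos_drift_mm` from calibration (or a foot
#' leaves the mat), `foot_orientation` when a toe angle leaves the allowed
#' band or drifts more than `angle_drift_deg` from calibration, and
#' `lr_imbalance` when the left/right load imbalance exceeds
#' `lr_balance_max`. The state is `Ms` iff no flag is raised.
#'
#' @param frame A filtered full [pressure_frame()].
#' @param profile A [calibrate()]d `calibration_profile`.
#' @param thresholds A [stance_thresholds()].
#' @param monitor A [monitor_params()].
#' @param config A [sensor_config()].
#' @param on_missing_foot `"error"` to stop when a half-frame is empty,
#'   `"flag"` (used in streaming) to record it as a `foot_position` flag.
#' @return A `frame_assessment`: list with `state` (`"Ms"`/`"Mp"`), `flags`
#'   (character), `lean_severity`, `lean_direction` (unit vector of the
#'   overall-COP displacement), `displacement_norm` (max normalised `d`
#'   over the three COPs), per-COP `d_overall`, `d_left`, `d_right`, the
#'   measured COPs and foot regions, and `timestamp_ms`.
#' @export
assess_frame <- function(frame, profile,
                         thresholds = stance_thresholds(),
                         monitor = monitor_params(),
                         config = sensor_config(),
                         on_missing_foot = c("error", "flag")) {
  on_missing_foot <- match.arg(on_missing_foot)
  ts <- attr(frame, "timestamp_ms")
  halves <- split_left_right(frame, config)
  missing <- total_pressure(halves$left) <= 0 || total_pressure(halves$right) <= 0

  if (missing) {
    if (on_missing_foot == "error") {
      stop("missing foot: a half-frame carries no load", call. = FALSE)
    }
    return(new_assessment(
      flags = "foot_position", severity = "broken",
      lean_direction = c(0, 0), displacement_norm = Inf,
      d = c(Inf, Inf, Inf), cops = NULL, feet = NULL, monitor = monitor,
      timestamp_ms = ts))
  }

  cop_o <- compute_cop(frame, config)
  left <- detect_foot(halves$left, config)
  right <- detect_foot(halves$right, config)
  m <- stance_metrics(left, right, config)

  t_o <- cop_region_test(cop_o, profile$cop_o_ref, profile$alpha_mm,
                         monitor$region_mode)
  t_l <- cop_region_test(left$centroid, profile$cop_l_ref, profile$alpha_mm,
                         monitor$region_mode)
  t_r <- cop_region_test(right$centroid, profile$cop_r_ref, profile$alpha_mm,
                         monitor$region_mode)

  dist_mm <- function(a, b) sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  pos_drift <- max(dist_mm(left$centroid, profile$foot_left$centroid),
                   dist_mm(right$centroid, profile$foot_right$centroid))
  in_band <- function(a) a >= thresholds$toe_angle_min_deg &
                         a <= thresholds$toe_angle_max_deg
  angle_drift <- max(abs(left$toe_angle_deg - profile$foot_left$toe_angle_deg),
                     abs(right$toe_angle_deg - profile$foot_right$toe_angle_deg))

  flags <- character()
  if (!t_o$inside) flags <- c(flags, "cop_overall")
  if (!t_l$inside) flags <- c(flags, "cop_left")
  if (!t_r$inside) flags <- c(flags, "cop_right")
  if (pos_drift > monitor$pos_drift_mm) flags <- c(flags, "foot_position")
  if (!in_band(left$toe_angle_deg) || !in_band(right$toe_angle_deg) ||
      angle_drift > monitor$angle_drift_deg) {
    flags <- c(flags, "foot_orientation")
  }
  if (m$lr_balance > thresholds$lr_balance_max) {
    flags <- c(flags, "lr_imbalance")
  }

  delta <- c(cop_o$x - profile$cop_o_ref$x, cop_o$y - profile$cop_o_ref$y)
  nrm <- sqrt(sum(delta^2))
  lean_dir <- if (nrm > 0) delta / nrm else c(0, 0)
  d_norm <- max(t_o$d, t_l$d, t_r$d)

  new_assessment(
    flags = flags,
    severity = as.character(lean_severity(d_norm, monitor$lean_bands)),
    lean_direction = lean_dir, displacement_norm = d_norm,
    d = c(t_o$d, t_l$d, t_r$d),
    cops = list(overall = cop_o, left = left$centroid, right = right$centroid),
    feet = list(left = left, right = right),
    monitor = monitor, timestamp_ms = ts)
}

new_assessment <- function(flags, severity, lean_direction, displacement_norm,
                           d, cops, feet, monitor, timestamp_ms) {
  structure(
    list(
      state = if (length(flags)) "Mp" else "Ms",
      flags = flags,
      lean_severity = factor(severity,
                             levels = c("balanced", "slight", "severe",
                                        "broken"),
                             ordered = TRUE),
      lean_direction = lean_direction,
      displacement_norm = displacement_norm,
      d_overall = d[1], d_left = d[2], d_right = d[3],
      cops = cops, feet = feet,
      timestamp_ms = timestamp_ms
    ),
    class = "frame_assessment"
  )
}

#' @export
print.frame_assessment <- function(x, ...) {
  cat(sprintf("<frame_assessment> state = %s, severity = %s, d = %.3f%s\n",
              x$state, as.character(x$lean_severity), x$displacement_norm,
              if (length(x$flags))
                paste0(", flags: ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.frame_assessment <- function(x, ...) {
  tibble::tibble(
    timestamp_ms = x$timestamp_ms,
    state = x$state,
    severity = as.character(x$lean_severity),
    flags = paste(x$flags, collapse = ";"),
    d_overall = x$d_overall, d_left = x$d_left, d_right = x$d_right,
    displacement_norm = x$displacement_norm,
    lean_dir_x = x$lean_direction[1], lean_dir_y = x$lean_direction[2],
    cop_o_x = if (is.null(x$cops)) NA_real_ else x$cops$overall$x,
    cop_o_y = if (is.null(x$cops)) NA_real_ else x$cops$overall$y
  )
}

#' Create an empty training session record
#'
#' @param fps Frame rate of the stream (frames per second).
#' @param debounce Consecutive poor frames required to break; see
#'   [monitor_params()].
#' @param participant_id Optional participant identifier.
#' @param condition Optional feedback condition label (`"NFB"`, `"CFB"`,
#'   `"GFB"`).
#' @param phase Starting phase; [run_session()] starts at `"ENTRY"`, direct
#'   use of [session_step()] assumes `"TRAINING"`.
#' @return A `session_record`.
#' @export
new_session <- function(fps = monitor_params()$fps, debounce = 1L,
                        participant_id = NA_character_,
                        condition = NA_character_,
                        phase = c("TRAINING", "ENTRY")) {
  phase <- match.arg(phase)
  structure(
    list(
      phase = phase, aborted = FALSE, abort_reason = NA_character_,
      fps = fps, debounce = as.integer(debounce),
      frames_seen = 0L, good_frames = 0L, mp_streak = 0L,
      good_duration_s = 0, break_time_s = NA_real_,
      terminal_flags = character(),
      participant_id = participant_id, condition = condition,
      final_level = NA_integer_, final_group = NA_character_,
      events = list(), log = list()
    ),
    class = "session_record"
  )
}

#' Advance a session by one assessed frame
#'
#' A good frame (`Ms`) adds one frame period (`1 / fps` seconds) to the
#' held-posture timer. Once `debounce` consecutive poor frames (`Mp`) are
#' seen, the session transitions to the terminal `BROKEN` phase: the timer
#' freezes, the break time is recorded and a notification event is emitted
#' (the headless stand-in for the in-game sound). Stepping a `BROKEN`
#' session is a no-op that emits a warning event.
#'
#' @param record A `session_record` in the `TRAINING` phase.
#' @param assessment A `frame_assessment` from [assess_frame()].
#' @return The updated `session_record`.
#' @export
session_step <- function(record, assessment) {
  if (record$phase == "BROKEN") {
    warning("session already BROKEN; frame ignored", call. = FALSE)
    record$events <- c(record$events,
                       list(list(event = "step_after_break",
                                 t_s = record$break_time_s)))
    return(record)
  }
  if (record$phase != "TRAINING") {
    stop("session_step() requires a session in the TRAINING phase",
         call. = FALSE)
  }
  record$frames_seen <- record$frames_seen + 1L
  if (assessment$state == "Ms") {
    record$good_frames <- record$good_frames + 1L
    record$mp_streak <- 0L
  } else {
    record$mp_streak <- record$mp_streak + 1L
    if (record$mp_streak >= record$debounce) {
      record$phase <- "BROKEN"
      record$break_time_s <- (record$frames_seen - 1L) / record$fps
      record$terminal_flags <- assessment$flags
      record$events <- c(record$events,
                         list(list(event = "break_notification",
                                   t_s = record$break_time_s,
                                   flags = assessment$flags)))
    }
  }
  record$good_duration_s <- record$good_frames / record$fps
  if (record$phase == "BROKEN") {
    record$final_level <- level_for_duration(record$good_duration_s)
    record$final_group <- group_for_level(record$final_level)
  }
  record
}

#' Run a full monitored session over a frame stream
#'
#' Replays a stream of raw frames through the complete pipeline: each frame
#' is beta-filtered; during the entry phase frames are checked with
#' [validate_entry_stance()] and training begins at the first frame that
#' passes (that frame is also the first assessed training frame). Training
#' frames are classified with [assess_frame()] and fed to [session_step()]
#' until the stance breaks, which ends the session. A per-frame event log
#' is kept and can be written as JSONL. The run is deterministic given the
#' stream.
#'
#' @param frames List of raw [pressure_frame()]s (or file paths readable by
#'   [read_frame()]).
#' @param profile A `calibration_profile`.
#' @param thresholds A [stance_thresholds()].
#' @param monitor A [monitor_params()].
#' @param config A [sensor_config()].
#' @param beta Filter threshold (raw units).
#' @param participant_id,condition Metadata stored on the record.
#' @param log_path Optional path; when given the per-frame log is written
#'   as one JSON object per line.
#' @return A `session_record` whose `log` component is a per-frame tibble.
#'   If the stream ends before the entry stance is ever valid the record is
#'   marked `aborted`.
#' @export
run_session <- function(frames, profile,
                        thresholds = stance_thresholds(),
                        monitor = monitor_params(),
                        config = sensor_config(),
                        beta = default_beta(config),
                        participant_id = NA_character_,
                        condition = NA_character_,
                        log_path = NULL) {
  record <- new_session(fps = monitor$fps, debounce = monitor$debounce,
                        participant_id = participant_id,
                        condition = condition, phase = "ENTRY")
  log_rows <- vector("list", length(frames))
  n_logged <- 0L

  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.character(fr)) fr <- read_frame(fr, config)
    fr <- filter_frame(fr, beta)
    ts <- attr(fr, "timestamp_ms")

    if (record$phase == "ENTRY") {
      ok <- tryCatch(
        attr(validate_entry_stance(fr, thresholds, config), "overall_pass"),
        error = function(e) FALSE)
      if (!ok) {
        n_logged <- n_logged + 1L
        log_rows[[n_logged]] <- tibble::tibble(
          frame = i, timestamp_ms = ts, phase = "ENTRY",
          state = NA_character_, severity = NA_character_, flags = "",
          d_overall = NA_real_, d_left = NA_real_, d_right = NA_real_,
          displacement_norm = NA_real_,
          lean_dir_x = NA_real_, lean_dir_y = NA_real_,
          cop_o_x = NA_real_, cop_o_y = NA_real_)
        next
      }
      record$phase <- "TRAINING"
      record$events <- c(record$events,
                         list(list(event = "entry_passed",
                                   t_s = (i - 1L) / monitor$fps)))
    }

    a <- assess_frame(fr, profile, thresholds, monitor, config,
                      on_missing_foot = "flag")
    record <- session_step(record, a)
    n_logged <- n_logged + 1L
    log_rows[[n_logged]] <- dplyr::bind_cols(
      tibble::tibble(frame = i, phase = record$phase),
      tidy(a))
    if (record$phase == "BROKEN") break
  }

  if (record$phase == "ENTRY") {
    record$aborted <- TRUE
    record$abort_reason <- "stream ended before a valid entry stance"
  }
  record$log <- dplyr::bind_rows(log_rows[seq_len(n_logged)])
  if (record$phase != "BROKEN" && !record$aborted) {
    record$final_level <- level_for_duration(record$good_duration_s)
    record$final_group <- group_for_level(record$final_level)
  }
  if (!is.null(log_path)) {
    con <- file(log_path, open = "wt")
    on.exit(close(con))
    for (j in seq_len(nrow(record$log))) {
      writeLines(jsonlite::toJSON(as.list(record$log[j, ]),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
    }
  }
  record
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> phase = %s%s, held %.2f s (%d frames @ %g fps), level %s (%s)\n",
    x$phase, if (x$aborted) " (aborted)" else "",
    x$good_duration_s, x$good_frames, x$fps,
    ifelse(is.na(x$final_level), "-", x$final_level),
    ifelse(is.na(x$final_group), "-", x$final_group)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.session_record <- function(x, ...) {
  if (is.data.frame(x$log)) x$log else dplyr::bind_rows(x$log)
}

#' @exportS3Method generics::glance
glance.session_record <- function(x, ...) {
  tibble::tibble(
    phase = x$phase,
    aborted = x$aborted,
    good_duration_s = x$good_duration_s,
    break_time_s = x$break_time_s,
    frames_seen = x$frames_seen,
    fps = x$fps,
    final_level = x$final_level,
    final_group = x$final_group,
    terminal_flags = paste(x$terminal_flags, collapse = ";"),
    participant_id = x$participant_id,
    condition = x$condition
  )
}

#' Timeline plot of a monitored session
#'
#' @param object A `session_record`.
#' @param ... Unused.
#' @return A ggplot object: normalised COP displacement over time, coloured
#'   by lean severity, with the region boundary at `d = 1`.
#' @exportS3Method ggplot2::autoplot
autoplot.session_record <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$displacement_norm), ]
  df$t_s <- df$timestamp_ms / 1000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$displacement_norm,
                                   colour = .data$severity)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "normalised COP displacement d",
                  colour = "severity")
}
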