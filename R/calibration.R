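#' Validate an entry stance against the five criteria
#'
#' A wide horse stance is accepted for calibration/training only when all
#' five criteria hold: (1) left/right load balanced, (2) both feet on the
#' mat's horizontal centre-line, (3) feet wider than the minimum stance
#' width, (4) both feet slightly pointing outwards (toe-out within the 0-45
#' degree band by default, bounds inclusive), and (5) heel and forefoot
#' pressure balanced on each foot. Thresholds come from
#' [stance_thresholds()].
#'
#' @param frame A filtered full [pressure_frame()] with both feet on the mat.
#' @param thresholds A [stance_thresholds()].
#' @param config A [sensor_config()].
#' @return A `criteria_report`: a tibble with one row per criterion
#'   (`criterion`, `measured`, `bound`, `pass`) carrying attributes
#'   `overall_pass` (logical), `left` and `right` (the detected
#'   `foot_region`s) and `metrics` (the [stance_metrics()] row).
#' @examples
#' fr <- synth_frame(stance_spec())$frame
#' rep <- validate_entry_stance(filter_frame(fr))
#' attr(rep, "overall_pass")
#' @export
validate_entry_stance <- function(frame, thresholds = stance_thresholds(),
                                  config = sensor_config()) {
  halves <- split_left_right(frame, config)
  if (total_pressure(halves$left) <= 0 || total_pressure(halves$right) <= 0) {
    stop("missing foot: both halves of the mat must carry load", call. = FALSE)
  }
  left <- detect_foot(halves$left, config)
  right <- detect_foot(halves$right, config)
  m <- stance_metrics(left, right, config)

  angle_ok <- function(a) {
    a >= thresholds$toe_angle_min_deg & a <= thresholds$toe_angle_max_deg
  }
  hf_imb <- function(f) abs(f$heel_load_frac - f$fore_load_frac)

  report <- tibble::tibble(
    criterion = c("lr_balance", "centerline", "stance_width", "toe_angle",
                  "heel_fore"),
    measured = c(
      m$lr_balance,
      max(m$centerline_offset_left_mm, m$centerline_offset_right_mm),
      m$stance_width_mm,
      max(left$toe_angle_deg, right$toe_angle_deg),
      max(hf_imb(left), hf_imb(right))
    ),
    bound = c(
      thresholds$lr_balance_max,
      thresholds$centerline_tol_mm,
      thresholds$min_stance_width_mm,
      thresholds$toe_angle_max_deg,
      thresholds$heel_fore_imbalance_max
    ),
    pass = c(
      m$lr_balance <= thresholds$lr_balance_max,
      m$centerline_offset_left_mm <= thresholds$centerline_tol_mm &&
        m$centerline_offset_right_mm <= thresholds$centerline_tol_mm,
      m$stance_width_mm >= thresholds$min_stance_width_mm,
      angle_ok(left$toe_angle_deg) && angle_ok(right$toe_angle_deg),
      hf_imb(left) <= thresholds$heel_fore_imbalance_max &&
        hf_imb(right) <= thresholds$heel_fore_imbalance_max
    )
  )
  structure(report,
            overall_pass = all(report$pass),
            left = left, right = right, metrics = m,
            class = c("criteria_report", class(report)))
}

#' Capture a calibration profile from a valid stance
#'
#' Runs [validate_entry_stance()] on the calibration frame and, if the
#' stance passes, freezes the three reference COPs (overall, left, right),
#' the foot geometry and the valid-region radius `alpha_mm` into a profile
#' used by the monitor. If any criterion fails the calibration must be
#' redone: a condition of class `stancemat_redo_calibration` is signalled,
#' carrying the `criteria_report` in its `report` field.
#'
#' Several frames may be supplied (an averaging window): their cell-wise
#' mean (rounded) is calibrated, which damps sensor noise. Default is a
#' single frame.
#'
#' @param frames A filtered [pressure_frame()] or a list of them.
#' @param thresholds A [stance_thresholds()].
#' @param alpha_mm Valid-region radius (mm); see [monitor_params()].
#' @param config A [sensor_config()].
#' @return A `calibration_profile`: list with `cop_o_ref`, `cop_l_ref`,
#'   `cop_r_ref` (cop_points), `alpha_mm`, `foot_left`, `foot_right`
#'   (`foot_region`s) and `captured_at` (the frame timestamp, ms).
#' @export
calibrate <- function(frames, thresholds = stance_thresholds(),
                      alpha_mm = monitor_params()$alpha_mm,
                      config = sensor_config()) {
  stopifnot(alpha_mm > 0)
  frame <- if (inherits(frames, "pressure_frame")) frames else {
    stopifnot(length(frames) >= 1L)
    avg <- Reduce(`+`, lapply(frames, function(f) unclass(f) / length(frames)))
    pressure_frame(round(avg), config,
                   timestamp_ms = attr(frames[[1L]], "timestamp_ms"),
                   role = "calibration")
  }
  report <- validate_entry_stance(frame, thresholds, config)
  if (!attr(report, "overall_pass")) {
    failed <- report$criterion[!report$pass]
    rlang::abort(
      paste0("invalid entry stance, redo calibration (failed: ",
             paste(failed, collapse = ", "), ")"),
      class = "stancemat_redo_calibration",
      report = report
    )
  }
  structure(
    list(
      cop_o_ref = compute_cop(frame, config),
      cop_l_ref = attr(report, "left")$centroid,
      cop_r_ref = attr(report, "right")$centroid,
      alpha_mm = alpha_mm,
      foot_left = attr(report, "left"),
      foot_right = attr(report, "right"),
      captured_at = attr(frame, "timestamp_ms")
    ),
    class = "calibration_profile"
  )
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_profile> alpha = %g mm\n",
           "  COPo (%.1f, %.1f)  COPl (%.1f, %.1f)  COPr (%.1f, %.1f)\n"),
    x$alpha_mm, x$cop_o_ref$x, x$cop_o_ref$y,
    x$cop_l_ref$x, x$cop_l_ref$y, x$cop_r_ref$x, x$cop_r_ref$y))
  invisible(x)
}

#' Read / write a calibration profile as JSON
#'
#' @param profile A `calibration_profile` from [calibrate()].
#' @param path File path of the JSON profile.
#' @return `read_profile()` returns the `calibration_profile`;
#'   `write_profile()` returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  ser_cop <- function(p) list(x = p$x, y = p$y, total_pressure = p$total_pressure)
  ser_foot <- function(f) {
    list(side = f$side, centroid = ser_cop(f$centroid),
         toe_angle_deg = f$toe_angle_deg,
         heel_load_frac = f$heel_load_frac, fore_load_frac = f$fore_load_frac,
         total_pressure = f$total_pressure, axis = f$axis,
         bbox = as.list(f$bbox), n_cells = f$n_cells)
  }
  obj <- list(
    cop_o_ref = ser_cop(profile$cop_o_ref),
    cop_l_ref = ser_cop(profile$cop_l_ref),
    cop_r_ref = ser_cop(profile$cop_r_ref),
    alpha_mm = profile$alpha_mm,
    foot_left = ser_foot(profile$foot_left),
    foot_right = ser_foot(profile$foot_right),
    captured_at = profile$captured_at
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_cop <- function(p) cop_point(p$x, p$y, p$total_pressure)
  de_foot <- function(f) {
    structure(
      list(side = f$side, centroid = de_cop(f$centroid),
           toe_angle_deg = f$toe_angle_deg,
           heel_load_frac = f$heel_load_frac,
           fore_load_frac = f$fore_load_frac,
           total_pressure = f$total_pressure, axis = unlist(f$axis),
           bbox = unlist(f$bbox), n_cells = f$n_cells),
      class = "foot_region")
  }
  structure(
    list(
      cop_o_ref = de_cop(obj$cop_o_ref),
      cop_l_ref = de_cop(obj$cop_l_ref),
      cop_r_ref = de_cop(obj$cop_r_ref),
      alpha_mm = obj$alpha_mm,
      foot_left = de_foot(obj$foot_left),
      foot_right = de_foot(obj$foot_right),
      captured_at = obj$captured_at
    ),
    class = "calibration_profile"
  )
}
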