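#' Sensor-mat configuration
#'
#' Describes the geometry and resolution of the pressure-sensing mat: a grid
#' of `rows x cols` piezoresistive cells covering a `length_mm x width_mm`
#' surface, each cell read at `bit_depth` bits. The default is the 924-cell
#' 12-bit mat (22 rows x 42 columns over 1000 x 500 mm) used for horse-stance
#' training.
#'
#' Coordinates: `x` runs along the 1000 mm axis (medio-lateral, increasing
#' left to right from the practitioner's view) and `y` along the 500 mm axis
#' (posterior to anterior). Cell centres sit at `(col - 0.5) * pitch_x` and
#' `(row - 0.5) * pitch_y` with 1-based indices.
#'
#' @param rows,cols Grid dimensions (rows x cols cells).
#' @param length_mm,width_mm Physical extent of the sensing surface in mm.
#'   `x` spans `length_mm` (columns), `y` spans `width_mm` (rows).
#' @param bit_depth Bits per raw reading; raw values lie in
#'   `[0, 2^bit_depth - 1]`.
#'
#' @return An object of class `sensor_config` (a named list with the fields
#'   above plus derived `pitch_x`, `pitch_y` and `max_raw`).
#' @examples
#' cfg <- sensor_config()
#' cfg$rows * cfg$cols   # 924 sensing cells
#' cfg$max_raw           # 4095 at 12 bit
#' @export
sensor_config <- function(rows = 22L, cols = 42L,
                          length_mm = 1000, width_mm = 500,
                          bit_depth = 12L) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  bit_depth <- as.integer(bit_depth)
  stopifnot(rows >= 1L, cols >= 1L, length_mm > 0, width_mm > 0,
            bit_depth >= 1L, bit_depth <= 30L)
  structure(
    list(
      rows = rows, cols = cols,
      length_mm = length_mm, width_mm = width_mm,
      bit_depth = bit_depth,
      pitch_x = length_mm / cols,
      pitch_y = width_mm / rows,
      max_raw = 2L^bit_depth - 1L
    ),
    class = "sensor_config"
  )
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf(
    "<sensor_config> %d x %d cells (%d total), %d-bit, %g x %g mm (pitch %.2f x %.2f mm)\n",
    x$rows, x$cols, x$rows * x$cols, x$bit_depth,
    x$length_mm, x$width_mm, x$pitch_x, x$pitch_y
  ))
  invisible(x)
}

#' Default raw-noise filter threshold
#'
#' The zeroing high-pass filter removes the preload of the mat's foam layers
#' and residual electronic noise. The default threshold is 2% of full scale
#' (81.9 raw units for a 12-bit mat).
#'
#' @param config A [sensor_config()].
#' @return A single non-negative number (raw units).
#' @export
default_beta <- function(config = sensor_config()) {
  0.02 * config$max_raw
}

#' Entry-stance validation thresholds
#'
#' Thresholds for the five entry criteria of a correct wide horse stance:
#' \enumerate{
#'   \item left/right load balance: `|Pl - Pr| / (Pl + Pr) <= lr_balance_max`;
#'   \item both foot centroids within `centerline_tol_mm` of the mat's
#'     horizontal centre-line (`y = width_mm / 2`);
#'   \item stance width (distance between foot centroids)
#'     `>= min_stance_width_mm` (a fixed proxy for "wider than
#'     shoulder-width"; pass `shoulder_width_mm` to use `1.2 x` a measured
#'     per-user value instead);
#'   \item both toe-out angles within `[toe_angle_min_deg, toe_angle_max_deg]`
#'     (inclusive), default 0 to 45 degrees of outward rotation;
#'   \item both heel/forefoot imbalances `|heel - fore| <=
#'     heel_fore_imbalance_max`.
#' }
#'
#' @param lr_balance_max Maximum left/right load imbalance (fraction, 0-1).
#' @param centerline_tol_mm Maximum centroid offset from the centre-line (mm).
#' @param min_stance_width_mm Minimum distance between foot centroids (mm).
#' @param toe_angle_min_deg,toe_angle_max_deg Inclusive outward toe-angle
#'   bounds (degrees).
#' @param heel_fore_imbalance_max Maximum `|heel_frac - fore_frac|` per foot.
#' @param shoulder_width_mm Optional measured shoulder width; when given,
#'   the stance-width requirement becomes `1.2 * shoulder_width_mm`.
#' @return An object of class `stance_thresholds`.
#' @export
stance_thresholds <- function(lr_balance_max = 0.15,
                              centerline_tol_mm = 40,
                              min_stance_width_mm = 400,
                              toe_angle_min_deg = 0,
                              toe_angle_max_deg = 45,
                              heel_fore_imbalance_max = 0.30,
                              shoulder_width_mm = NULL) {
  stopifnot(lr_balance_max >= 0, centerline_tol_mm >= 0,
            min_stance_width_mm >= 0, heel_fore_imbalance_max >= 0,
            toe_angle_min_deg < toe_angle_max_deg)
  if (!is.null(shoulder_width_mm)) {
    stopifnot(shoulder_width_mm > 0)
    min_stance_width_mm <- 1.2 * shoulder_width_mm
  }
  structure(
    list(
      lr_balance_max = lr_balance_max,
      centerline_tol_mm = centerline_tol_mm,
      min_stance_width_mm = min_stance_width_mm,
      toe_angle_min_deg = toe_angle_min_deg,
      toe_angle_max_deg = toe_angle_max_deg,
      heel_fore_imbalance_max = heel_fore_imbalance_max
    ),
    class = "stance_thresholds"
  )
}

#' Monitoring parameters
#'
#' Parameters of the real-time good/poor posture monitor.
#'
#' @param alpha_mm Radius of the valid COP region around each calibrated
#'   reference COP (mm). Displacements are normalised by `alpha_mm`.
#' @param region_mode `"box"` applies strict per-axis bounds
#'   (`|dx| < alpha` and `|dy| < alpha`); `"circle"` uses the Euclidean
#'   distance. The box is the default; the circular region it circumscribes
#'   is selectable.
#' @param pos_drift_mm Maximum allowed drift of a foot centroid from its
#'   calibrated position before a `foot_position` flag is raised (mm).
#' @param angle_drift_deg Maximum allowed toe-angle drift from calibration
#'   before a `foot_orientation` flag is raised (degrees).
#' @param debounce Number of consecutive poor-posture frames required to
#'   declare the stance broken (1 = first poor frame breaks).
#' @param fps Frame rate of the acquisition stream (frames per second).
#' @param lean_bands Increasing break points, on the normalised displacement
#'   `d`, between the `balanced`/`slight`/`severe`/`broken` feedback states:
#'   balanced for `d <= lean_bands[1]`, slight up to `lean_bands[2]`, severe
#'   below `lean_bands[3]`, broken at or above `lean_bands[3]`.
#' @return An object of class `monitor_params`.
#' @export
monitor_params <- function(alpha_mm = 40,
                           region_mode = c("box", "circle"),
                           pos_drift_mm = 50,
                           angle_drift_deg = 15,
                           debounce = 1L,
                           fps = 20,
                           lean_bands = c(0.4, 0.75, 1)) {
  region_mode <- match.arg(region_mode)
  stopifnot(alpha_mm > 0, pos_drift_mm >= 0, angle_drift_deg >= 0,
            debounce >= 1L, fps > 0,
            length(lean_bands) == 3L, !is.unsorted(lean_bands),
            lean_bands[1] >= 0)
  structure(
    list(
      alpha_mm = alpha_mm, region_mode = region_mode,
      pos_drift_mm = pos_drift_mm, angle_drift_deg = angle_drift_deg,
      debounce = as.integer(debounce), fps = fps,
      lean_bands = lean_bands
    ),
    class = "monitor_params"
  )
}

#' Read / write a flat key-value configuration file
#'
#' The configuration file is plain text with one `key = value` entry per line
#' (`#` starts a comment). Recognised keys: `rows`, `cols`, `length_mm`,
#' `width_mm`, `bit_depth`, `beta`, `alpha`, `region_mode`, plus any field
#' name of [stance_thresholds()] and [monitor_params()]. Unknown keys are an
#' error.
#'
#' @param path Path of the configuration file.
#' @return For `read_mat_config()`: a list with components `config`
#'   ([sensor_config()]), `beta` (filter threshold), `thresholds`
#'   ([stance_thresholds()]) and `monitor` ([monitor_params()]).
#' @export
read_mat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  names(vals) <- keys

  cfg_keys <- c("rows", "cols", "length_mm", "width_mm", "bit_depth")
  thr_keys <- c("lr_balance_max", "centerline_tol_mm", "min_stance_width_mm",
                "toe_angle_min_deg", "toe_angle_max_deg",
                "heel_fore_imbalance_max", "shoulder_width_mm")
  mon_keys <- c("alpha", "region_mode", "pos_drift_mm", "angle_drift_deg",
                "debounce", "fps")
  known <- c(cfg_keys, thr_keys, mon_keys, "beta",
             "lean_band_balanced", "lean_band_slight", "lean_band_severe")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  pick_num <- function(set) {
    hit <- intersect(set, keys)
    stats::setNames(lapply(vals[hit], as.numeric), hit)
  }
  config <- do.call(sensor_config, pick_num(cfg_keys))
  thresholds <- do.call(stance_thresholds, pick_num(thr_keys))

  mon_args <- pick_num(setdiff(mon_keys, "region_mode"))
  names(mon_args)[names(mon_args) == "alpha"] <- "alpha_mm"
  if ("region_mode" %in% keys) mon_args$region_mode <- vals[["region_mode"]]
  bands <- monitor_params()$lean_bands
  band_keys <- c("lean_band_balanced", "lean_band_slight", "lean_band_severe")
  for (i in seq_along(band_keys)) {
    if (band_keys[i] %in% keys) bands[i] <- as.numeric(vals[[band_keys[i]]])
  }
  mon_args$lean_bands <- bands
  monitor <- do.call(monitor_params, mon_args)

  beta <- if ("beta" %in% keys) as.numeric(vals[["beta"]]) else default_beta(config)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)

  list(config = config, beta = beta, thresholds = thresholds, monitor = monitor)
}

#' @rdname read_mat_config
#' @param config A [sensor_config()].
#' @param beta Filter threshold (raw units).
#' @param thresholds A [stance_thresholds()].
#' @param monitor A [monitor_params()].
#' @return For `write_mat_config()`: `path`, invisibly.
#' @export
write_mat_config <- function(path, config = sensor_config(),
                             beta = default_beta(config),
                             thresholds = stance_thresholds(),
                             monitor = monitor_params()) {
  fmt <- function(x) format(x, digits = 15, scientific = FALSE)
  lines <- c(
    sprintf("rows = %d", config$rows),
    sprintf("cols = %d", config$cols),
    sprintf("length_mm = %s", fmt(config$length_mm)),
    sprintf("width_mm = %s", fmt(config$width_mm)),
    sprintf("bit_depth = %d", config$bit_depth),
    sprintf("beta = %s", fmt(beta)),
    sprintf("alpha = %s", fmt(monitor$alpha_mm)),
    sprintf("region_mode = %s", monitor$region_mode),
    sprintf("pos_drift_mm = %s", fmt(monitor$pos_drift_mm)),
    sprintf("angle_drift_deg = %s", fmt(monitor$angle_drift_deg)),
    sprintf("debounce = %d", monitor$debounce),
    sprintf("fps = %s", fmt(monitor$fps)),
    sprintf("lean_band_balanced = %s", fmt(monitor$lean_bands[1])),
    sprintf("lean_band_slight = %s", fmt(monitor$lean_bands[2])),
    sprintf("lean_band_severe = %s", fmt(monitor$lean_bands[3])),
    sprintf("lr_balance_max = %s", fmt(thresholds$lr_balance_max)),
    sprintf("centerline_tol_mm = %s", fmt(thresholds$centerline_tol_mm)),
    sprintf("min_stance_width_mm = %s", fmt(thresholds$min_stance_width_mm)),
    sprintf("toe_angle_min_deg = %s", fmt(thresholds$toe_angle_min_deg)),
    sprintf("toe_angle_max_deg = %s", fmt(thresholds$toe_angle_max_deg)),
    sprintf("heel_fore_imbalance_max = %s", fmt(thresholds$heel_fore_imbalance_max))
  )
  writeLines(lines, path)
  invisible(path)
}
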