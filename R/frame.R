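#' Pressure frames
#'
#' A `pressure_frame` is one timestamped snapshot of the mat: a matrix of
#' non-negative integer raw pressure readings, one per sensing cell. Frames
#' play several roles in the pipeline: the calibration frame, real-time
#' training frames, and the left/right half-frames produced by
#' [split_left_right()]. Half-frames keep a column offset so that cell
#' coordinates stay in the full-mat frame of reference.
#'
#' @param values Integer matrix, `rows x cols` (or a half-frame slice),
#'   values in `[0, 2^bit_depth - 1]`.
#' @param config A [sensor_config()]; used to validate shape and range.
#' @param timestamp_ms Acquisition time in milliseconds.
#' @param role One of `"calibration"`, `"training"`, `"left"`, `"right"`.
#' @param col_offset Number of full-mat columns to the left of this frame's
#'   first column (0 for full frames and left halves).
#'
#' @return An object of class `pressure_frame`: the value matrix with
#'   `timestamp_ms`, `role` and `col_offset` attributes.
#' @examples
#' cfg <- sensor_config()
#' m <- matrix(0L, cfg$rows, cfg$cols)
#' m[10, 12] <- 900L
#' fr <- pressure_frame(m, cfg)
#' total_pressure(fr)
#' @export
pressure_frame <- function(values, config = sensor_config(),
                           timestamp_ms = 0,
                           role = c("training", "calibration", "left", "right"),
                           col_offset = 0L) {
  role <- match.arg(role)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (any(values != round(values))) {
    stop("pressure values must be integers", call. = FALSE)
  }
  if (any(values < 0)) stop("pressure values must be non-negative", call. = FALSE)
  if (any(values > config$max_raw)) {
    stop("pressure value exceeds sensor range [0, ", config$max_raw, "]",
         call. = FALSE)
  }
  if (nrow(values) != config$rows) {
    stop("frame has ", nrow(values), " rows; config expects ", config$rows,
         call. = FALSE)
  }
  full_ok <- ncol(values) == config$cols && role %in% c("training", "calibration")
  half_ok <- role %in% c("left", "right") && ncol(values) <= config$cols
  if (!full_ok && !half_ok) {
    stop("frame has ", ncol(values), " columns; config expects ", config$cols,
         call. = FALSE)
  }
  structure(
    matrix(as.integer(values), nrow(values), ncol(values)),
    timestamp_ms = timestamp_ms,
    role = role,
    col_offset = as.integer(col_offset),
    class = c("pressure_frame", "matrix", "array")
  )
}

#' @export
print.pressure_frame <- function(x, ...) {
  cat(sprintf("<pressure_frame> %d x %d, role = %s, t = %g ms, total = %.0f\n",
              nrow(x), ncol(x), attr(x, "role"), attr(x, "timestamp_ms"),
              sum(x)))
  invisible(x)
}

#' Total raw pressure of a frame
#' @param frame A [pressure_frame()].
#' @return Sum of all raw cell values.
#' @export
total_pressure <- function(frame) sum(as.numeric(frame))

#' Read and write frame files
#'
#' Frame files are whitespace-delimited integer text: a header line
#' `# <rows> <cols> <timestamp_ms>` followed by `rows` lines of `cols`
#' space-separated integers.
#'
#' @param path File path.
#' @param config A [sensor_config()]; the file's shape must match.
#' @return `read_frame()` returns a [pressure_frame()]; `write_frame()`
#'   returns `path` invisibly.
#' @export
read_frame <- function(path, config = sensor_config()) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#")) {
    stop("malformed frame header (expected '# rows cols timestamp_ms')",
         call. = FALSE)
  }
  hdr <- scan(text = sub("^#", "", lines[1]), what = numeric(), quiet = TRUE)
  if (length(hdr) != 3L || any(is.na(hdr)) ||
      hdr[1] != round(hdr[1]) || hdr[2] != round(hdr[2])) {
    stop("malformed frame header (expected '# rows cols timestamp_ms')",
         call. = FALSE)
  }
  rows <- as.integer(hdr[1]); cols <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != rows) {
    stop("frame body has ", length(body), " rows; header declares ", rows,
         call. = FALSE)
  }
  cells <- scan(text = paste(body, collapse = "\n"), what = character(),
                quiet = TRUE)
  vals <- suppressWarnings(as.numeric(cells))
  if (any(is.na(vals)) || any(vals != round(vals))) {
    stop("non-integer cell value in frame file", call. = FALSE)
  }
  if (length(vals) != rows * cols) {
    stop("frame body has ", length(vals), " cells; header declares ",
         rows * cols, call. = FALSE)
  }
  m <- matrix(as.integer(vals), nrow = rows, ncol = cols, byrow = TRUE)
  if (rows != config$rows || cols != config$cols) {
    stop("frame shape ", rows, " x ", cols, " does not match config ",
         config$rows, " x ", config$cols, call. = FALSE)
  }
  pressure_frame(m, config, timestamp_ms = hdr[3])
}

#' @rdname read_frame
#' @param frame A [pressure_frame()] to write.
#' @export
write_frame <- function(frame, path) {
  hdr <- sprintf("# %d %d %s", nrow(frame), ncol(frame),
                 format(attr(frame, "timestamp_ms"), scientific = FALSE))
  body <- apply(unclass(frame), 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Zeroing high-pass filter
#'
#' Removes the foam-layer preload and residual noise from a raw frame: every
#' cell strictly below the threshold `beta` is set to zero, all other cells
#' pass unchanged. With `beta = 0` the frame is returned untouched. The
#' operation is idempotent and never increases a cell.
#'
#' @param frame A raw [pressure_frame()].
#' @param beta Threshold in raw units (`>= 0`); see [default_beta()].
#' @return The filtered [pressure_frame()].
#' @export
filter_frame <- function(frame, beta = default_beta()) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0)
  out <- unclass(frame)
  out[out < beta] <- 0L
  attributes(out) <- attributes(frame)
  out
}

#' Segment a frame into left and right half-frames
#'
#' In wide isometric stances the left foot rests on the left half of the mat
#' and the right foot on the right half, so segmentation is a column split:
#' the left half-frame takes columns `1 .. floor(cols / 2)` and the right
#' half-frame the remainder (for an odd column count the extra column goes to
#' the right half). Total pressure is conserved exactly, and half-frames
#' retain full-mat coordinates via their column offset.
#'
#' @param frame A filtered [pressure_frame()].
#' @param config A [sensor_config()].
#' @return A list with components `left` and `right`, both [pressure_frame()]s.
#' @export
split_left_right <- function(frame, config = sensor_config()) {
  nc <- ncol(frame)
  nl <- nc %/% 2L
  ts <- attr(frame, "timestamp_ms")
  list(
    left = pressure_frame(unclass(frame)[, seq_len(nl), drop = FALSE],
                          config, timestamp_ms = ts, role = "left",
                          col_offset = 0L),
    right = pressure_frame(unclass(frame)[, (nl + 1L):nc, drop = FALSE],
                           config, timestamp_ms = ts, role = "right",
                           col_offset = nl)
  )
}

#' Centre of pressure of a frame
#'
#' The centre of pressure (COP) is the pressure-weighted centroid of the
#' load distribution, in mat coordinates (mm): `x = sum(v * x_cell) / sum(v)`
#' over all cells, with cell centres at `(col - 0.5) * pitch_x` (plus the
#' half-frame column offset) and `(row - 0.5) * pitch_y`.
#'
#' @param frame A [pressure_frame()] (full or half) with positive total load.
#' @param config A [sensor_config()].
#' @return A `cop_point`: list with `x`, `y` (mm) and `total_pressure`.
#' @examples
#' cfg <- sensor_config()
#' m <- matrix(1L, cfg$rows, cfg$cols)
#' compute_cop(pressure_frame(m, cfg))  # mat centre: (500, 250)
#' @export
compute_cop <- function(frame, config = sensor_config()) {
  v <- as.numeric(frame)
  total <- sum(v)
  if (total <= 0) {
    stop("zero total pressure: no load on the mat", call. = FALSE)
  }
  xy <- cell_centers(frame, config)
  cop_point(sum(v * xy$x) / total, sum(v * xy$y) / total, total)
}

cop_point <- function(x, y, total_pressure) {
  structure(list(x = x, y = y, total_pressure = total_pressure),
            class = "cop_point")
}

#' @export
print.cop_point <- function(x, ...) {
  cat(sprintf("<cop_point> x = %.2f mm, y = %.2f mm, total = %.0f\n",
              x$x, x$y, x$total_pressure))
  invisible(x)
}

# Cell-centre coordinates (mm, full-mat frame) for every cell of a frame,
# column-major to match as.numeric(matrix).
cell_centers <- function(frame, config) {
  off <- attr(frame, "col_offset") %||% 0L
  cols <- (seq_len(ncol(frame)) + off - 0.5) * config$pitch_x
  rows <- (seq_len(nrow(frame)) - 0.5) * config$pitch_y
  list(x = rep(cols, each = nrow(frame)), y = rep(rows, ncol(frame)))
}

#' Mirror a frame left-right
#'
#' Reverses the column order, mapping cell-centre `x` to `length_mm - x`.
#' Useful for symmetry checks: the COP of a mirrored frame is the mirrored
#' COP.
#'
#' @inheritParams compute_cop
#' @return The mirrored [pressure_frame()].
#' @export
mirror_frame <- function(frame, config = sensor_config()) {
  out <- unclass(frame)[, rev(seq_len(ncol(frame))), drop = FALSE]
  attributes(out) <- attributes(frame)
  out
}

#' Frame as a tidy tibble
#'
#' One row per cell with grid indices, mat coordinates (mm) and raw value.
#'
#' @param x A [pressure_frame()].
#' @param config A [sensor_config()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x_mm`, `y_mm`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.pressure_frame <- function(x, config = sensor_config(), ...) {
  xy <- cell_centers(x, config)
  off <- attr(x, "col_offset") %||% 0L
  tibble::tibble(
    row = rep(seq_len(nrow(x)), ncol(x)),
    col = rep(seq_len(ncol(x)) + off, each = nrow(x)),
    x_mm = xy$x,
    y_mm = xy$y,
    value = as.integer(x)
  )
}

#' Heat-map plot of a pressure frame
#'
#' @param object A [pressure_frame()].
#' @param config A [sensor_config()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pressure_frame <- function(object, config = sensor_config(), ...) {
  df <- as_tibble.pressure_frame(object, config)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, config$max_raw)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "raw",
                  title = sprintf("Pressure frame (t = %g ms)",
                                  attr(object, "timestamp_ms")))
}
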