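#' Detect the foot in a half-frame
#'
#' Treats the loaded cells of a (filtered) half-frame as one plantar pressure
#' blob and extracts its geometry: the pressure-weighted centroid (identical
#' to the half-frame COP), the toe-out angle of the principal axis, the
#' heel/forefoot load split, the total load and the bounding box. One foot
#' per half-frame is assumed, which holds for wide isometric stances.
#'
#' Shape estimation (orientation, heel/forefoot split, bounding box) is
#' restricted to the dominant connected pressure blob: residual noise that
#' survives the beta filter shows up as isolated speckle cells, which are
#' excluded by a local-support rule before the heaviest connected component
#' is taken. The centroid and total load always use the whole half-frame.
#'
#' @param half A filtered left or right half [pressure_frame()] from
#'   [split_left_right()].
#' @param config A [sensor_config()].
#' @param side `"left"` or `"right"`; taken from the frame's role when
#'   omitted. The side fixes the outward-positive sign of the toe angle.
#' @return A `foot_region`: list with `side`, `centroid` (a `cop_point`),
#'   `toe_angle_deg`, `heel_load_frac`, `fore_load_frac`, `total_pressure`,
#'   `axis` (unit vector of the principal axis, anterior-pointing), `bbox`
#'   (named vector `row_min`, `row_max`, `col_min`, `col_max` in full-mat
#'   indices) and `n_cells`.
#' @export
detect_foot <- function(half, config = sensor_config(), side = NULL) {
  side <- side %||% switch(attr(half, "role"),
                           left = "left", right = "right",
                           stop("`side` must be given for non-half frames",
                                call. = FALSE))
  if (total_pressure(half) <= 0) {
    stop("empty half-frame: no foot present on the ", side, " half",
         call. = FALSE)
  }
  centroid <- compute_cop(half, config)
  mom <- blob_moments(half, config)
  axis <- principal_axis(mom)
  phi <- atan2(axis[1], axis[2]) * 180 / pi
  toe <- if (side == "left") -phi else phi

  hf <- heel_fore_from_axis(mom$blob, config,
                            cop_point(mom$mx, mom$my, 0), axis)

  off <- attr(half, "col_offset") %||% 0L
  loaded <- which(unclass(mom$blob) > 0, arr.ind = TRUE)
  bbox <- c(row_min = min(loaded[, 1]), row_max = max(loaded[, 1]),
            col_min = min(loaded[, 2]) + off, col_max = max(loaded[, 2]) + off)

  structure(
    list(
      side = side,
      centroid = centroid,
      toe_angle_deg = toe,
      heel_load_frac = hf[["heel"]],
      fore_load_frac = hf[["fore"]],
      total_pressure = centroid$total_pressure,
      axis = axis,
      bbox = bbox,
      n_cells = nrow(loaded)
    ),
    class = "foot_region"
  )
}

#' @export
print.foot_region <- function(x, ...) {
  cat(sprintf(
    "<foot_region> %s foot: centroid (%.1f, %.1f) mm, toe-out %.1f deg, heel/fore %.2f/%.2f, total %.0f\n",
    x$side, x$centroid$x, x$centroid$y, x$toe_angle_deg,
    x$heel_load_frac, x$fore_load_frac, x$total_pressure))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.foot_region <- function(x, ...) {
  tibble::tibble(
    side = x$side,
    centroid_x_mm = x$centroid$x,
    centroid_y_mm = x$centroid$y,
    toe_angle_deg = x$toe_angle_deg,
    heel_load_frac = x$heel_load_frac,
    fore_load_frac = x$fore_load_frac,
    total_pressure = x$total_pressure,
    n_cells = x$n_cells
  )
}

# 3x3 box sum with zero padding.
box_sum3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + p[di + seq_len(nr), dj + seq_len(nc)]
  }
  out
}

# The dominant pressure blob of a half-frame: residual sensor noise that
# survives the beta filter appears as isolated speckle, so shape estimation
# is restricted to (1) loaded cells with at least two loaded 8-neighbours,
# grouped into connected components (connectivity bridges one-cell gaps),
# of which (2) every component carrying at least 10% of the heaviest
# component's load is kept — so a lightly loaded forefoot lobe separated
# from the heel by a sub-threshold gap still counts as part of the foot,
# while speckle clusters never reach that weight. Returns the half with all
# other cells zeroed; NULL when fewer than 3 cells remain.
dominant_blob <- function(half) {
  m <- unclass(half)
  loaded <- m > 0
  supported <- loaded & (box_sum3(loaded) - loaded) >= 2
  if (sum(supported) < 3L) return(NULL)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(supported)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      i <- (frontier - 1L) %% nr + 1L
      j <- (frontier - 1L) %/% nr + 1L
      ii <- pmin(pmax(rep(i, 25L) + rep(-2:2, each = 5L * length(i)), 1L), nr)
      jj <- pmin(pmax(rep(j, 25L) + rep(rep(-2:2, each = length(i)), 5L), 1L), nc)
      q <- unique((jj - 1L) * nr + ii)
      q <- q[supported[q] & lab[q] == 0L]
      lab[q] <- cur
      frontier <- q
    }
  }
  weights <- vapply(seq_len(cur), function(k) sum(m[lab == k]), 0)
  keep <- lab %in% which(weights >= 0.1 * max(weights))
  if (sum(keep) < 3L) return(NULL)
  out <- m
  out[!keep] <- 0L
  attributes(out) <- attributes(half)
  out
}

# Pressure-weighted first and second central moments of the dominant blob.
# Moments weight each cell by its value minus the blob's minimum loaded
# value (background subtraction): cells hovering just above the filter
# threshold — the noisy rim — get almost no leverage, while the loaded core
# is barely changed, and a constant offset cannot bias the axis. Two
# trimming passes then drop cells beyond Mahalanobis distance 3 of the
# running estimate (robust moments), removing speckle that slipped into the
# component.
blob_moments <- function(half, config) {
  blob <- dominant_blob(half)
  if (is.null(blob)) {
    stop("degenerate blob: fewer than 3 supported cells", call. = FALSE)
  }
  v0 <- as.numeric(blob)
  keep <- v0 > 0
  xy <- cell_centers(blob, config)
  x <- xy$x[keep]; y <- xy$y[keep]
  v_raw <- v0[keep]
  v <- v_raw - min(v_raw) + 1e-6   # background-subtracted weights
  idx <- which(keep)

  moments_of <- function(sel) {
    w <- v[sel] / sum(v[sel])
    mx <- sum(w * x[sel]); my <- sum(w * y[sel])
    list(mx = mx, my = my,
         mxx = sum(w * (x[sel] - mx)^2),
         myy = sum(w * (y[sel] - my)^2),
         mxy = sum(w * (x[sel] - mx) * (y[sel] - my)))
  }
  sel <- rep(TRUE, length(v))
  m <- moments_of(sel)
  for (pass in 1:2) {
    det <- m$mxx * m$myy - m$mxy^2
    if (det <= 0) break
    dx <- x - m$mx; dy <- y - m$my
    d2 <- (m$myy * dx^2 - 2 * m$mxy * dx * dy + m$mxx * dy^2) / det
    sel_new <- d2 <= 9
    if (sum(sel_new) < 3L || all(sel_new == sel)) break
    sel <- sel_new
    m <- moments_of(sel)
  }
  out <- matrix(0L, nrow(blob), ncol(blob))
  out[idx[sel]] <- v_raw[sel]
  attributes(out) <- attributes(blob)
  c(m, list(blob = out))
}

# Anterior-pointing unit vector of the weighted principal axis.
principal_axis <- function(mom) {
  cov <- matrix(c(mom$mxx, mom$mxy, mom$mxy, mom$myy), 2L, 2L)
  e <- eigen(cov, symmetric = TRUE)
  if (e$values[2] <= 1e-9 * max(1, e$values[1])) {
    stop("degenerate blob: loaded cells are collinear", call. = FALSE)
  }
  v <- e$vectors[, 1]                       # (x, y) components, major axis
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  v / sqrt(sum(v^2))
}

#' Toe-out angle of a foot blob
#'
#' Estimates the foot's long axis as the pressure-weighted principal axis
#' (second central moments) of the loaded cells and reports its angle from
#' the anterior (`y`) axis. The 180-degree axis ambiguity is resolved by
#' taking the anterior-pointing direction; the sign is outward-positive for
#' the given side, so a foot rotated toward the mat edge has a positive
#' angle on either side. The result lies in (-90, 90).
#'
#' @inheritParams detect_foot
#' @return Toe-out angle in degrees.
#' @export
foot_orientation <- function(half, config = sensor_config(), side = NULL) {
  side <- side %||% switch(attr(half, "role"),
                           left = "left", right = "right",
                           stop("`side` must be given for non-half frames",
                                call. = FALSE))
  axis <- principal_axis(blob_moments(half, config))
  phi <- atan2(axis[1], axis[2]) * 180 / pi
  if (side == "left") -phi else phi
}

# Split load about the line through `centroid` perpendicular to `axis`.
heel_fore_from_axis <- function(half, config, centroid, axis) {
  v <- as.numeric(half)
  keep <- v > 0
  xy <- cell_centers(half, config)
  proj <- (xy$x[keep] - centroid$x) * axis[1] +
          (xy$y[keep] - centroid$y) * axis[2]
  w <- v[keep] / sum(v[keep])
  heel <- sum(w[proj < 0]) + 0.5 * sum(w[proj == 0])
  c(heel = heel, fore = 1 - heel)
}

#' Heel / forefoot load split
#'
#' Partitions the foot blob's load by the perpendicular to its principal
#' axis through the blob centroid: cells with a negative axial projection
#' (posterior side) count as heel, the rest as forefoot. Fractions sum to
#' one.
#'
#' @param region A `foot_region` from [detect_foot()].
#' @param half The half-frame the region was detected from.
#' @param config A [sensor_config()].
#' @return Named numeric vector `c(heel, fore)`.
#' @export
heel_fore_split <- function(region, half, config = sensor_config()) {
  mom <- blob_moments(half, config)
  heel_fore_from_axis(mom$blob, config, cop_point(mom$mx, mom$my, 0),
                      region$axis)
}

#' Two-foot stance metrics
#'
#' @param left,right `foot_region`s from [detect_foot()].
#' @param config A [sensor_config()].
#' @return One-row tibble with `stance_width_mm` (Euclidean distance between
#'   the two centroids), `centerline_offset_left_mm` and
#'   `centerline_offset_right_mm` (each centroid's distance from the mat's
#'   horizontal centre-line `y = width_mm / 2`) and `lr_balance`
#'   (`|Pl - Pr| / (Pl + Pr)`, 0 = perfectly balanced).
#' @export
stance_metrics <- function(left, right, config = sensor_config()) {
  cy <- config$width_mm / 2
  pl <- left$total_pressure; pr <- right$total_pressure
  tibble::tibble(
    stance_width_mm = sqrt((left$centroid$x - right$centroid$x)^2 +
                           (left$centroid$y - right$centroid$y)^2),
    centerline_offset_left_mm = abs(left$centroid$y - cy),
    centerline_offset_right_mm = abs(right$centroid$y - cy),
    lr_balance = abs(pl - pr) / (pl + pr)
  )
}
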