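# Shared fixtures: all synthetic, built in code.

default_cfg <- sensor_config()

# A small square mat config for hand-built matrices.
small_cfg <- function(n = 5L) sensor_config(rows = n, cols = n,
                                            length_mm = n * 20, width_mm = n * 20)

# Random full-size raw frame with a given fill density.
random_frame <- function(cfg = default_cfg, density = 0.3, max_val = cfg$max_raw) {
  m <- matrix(0L, cfg$rows, cfg$cols)
  n <- length(m)
  k <- max(3L, round(density * n))
  idx <- sample.int(n, k)
  m[idx] <- sample.int(max_val, k, replace = TRUE)
  pressure_frame(m, cfg)
}

# Double-loop weighted-sum COP oracle, deliberately naive.
cop_oracle <- function(frame, cfg) {
  off <- attr(frame, "col_offset")
  if (is.null(off)) off <- 0L
  sx <- 0; sy <- 0; tot <- 0
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      v <- frame[i, j]
      sx <- sx + v * (j + off - 0.5) * cfg$pitch_x
      sy <- sy + v * (i - 0.5) * cfg$pitch_y
      tot <- tot + v
    }
  }
  c(x = sx / tot, y = sy / tot, total = tot)
}

# Exhaustive Mann-Whitney oracle via the pair-count statistic: enumerates all
# assignments of the pooled values to the first sample and computes the tail
# probability of U_x directly from pair comparisons (an independent route from
# the rank-sum implementation).
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(a, b) {
    u <- 0
    for (xi in a) for (yj in b) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
  list(U = u_obs, p = p)
}

# Minimal stand-in assessment for driving session_step directly.
fake_assessment <- function(state, flags = if (state == "Mp") "cop_overall" else character()) {
  structure(list(state = state, flags = flags), class = "frame_assessment")
}

# Ideal filtered stance frame and its calibration profile.
ideal_frame <- function(...) {
  filter_frame(synth_frame(stance_spec(...))$frame)
}
ideal_profile <- function() calibrate(ideal_frame())
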