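#' Mann-Whitney U rank-sum test
#'
#' A from-scratch two-sample rank-sum test for comparing held-stance
#' durations between feedback conditions. Ranks are midranks (ties share
#' the average rank); `U_x = R_x - n_x (n_x + 1) / 2` with `R_x` the rank
#' sum of the first sample, and `U_x + U_y = n_x * n_y`. For small samples
#' (`n_x + n_y <= 12` by default) the p-value is exact, computed by
#' enumerating all `choose(n, n_x)` assignments of the pooled observations
#' to the first sample; otherwise a normal approximation with tie
#' correction and continuity correction is used. The two-sided p doubles
#' the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples (durations, seconds); both non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses by the sample-size cutoff.
#' @param exact_cutoff Combined sample size up to which the exact null
#'   distribution is enumerated.
#' @return A `rank_sum_test`: list with `U` (= `U_x`), `U_x`, `U_y`,
#'   `p_two_sided`, `n_x`, `n_y` and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_cutoff = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(c(x, y))) stop("samples must not contain NA", call. = FALSE)
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  r <- rank(c(x, y))                      # midranks
  u_x <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  u_y <- n_x * n_y - u_x
  use_exact <- exact %||% (n <= exact_cutoff)

  if (use_exact) {
    u_null <- exact_u_distribution(r, n_x)
    eps <- 1e-9
    p_lo <- mean(u_null <= u_x + eps)
    p_hi <- mean(u_null >= u_x - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n_x * n_y / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_x - mu - sign(u_x - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(
    list(U = u_x, U_x = u_x, U_y = u_y, p_two_sided = p,
         n_x = n_x, n_y = n_y, method = method),
    class = "rank_sum_test"
  )
}

# Null distribution of U_x over all assignments of the pooled midranks to
# the first sample (the exhaustive permutation distribution).
exact_u_distribution <- function(r, n_x) {
  combos <- combn(length(r), n_x)
  colSums(matrix(r[combos], nrow = n_x)) - n_x * (n_x + 1) / 2
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Rank-sum test: U = %g (n = %d, %d), p = %.4g [%s]\n",
              x$U, x$n_x, x$n_y, x$p_two_sided, x$method))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(U = x$U, U_x = x$U_x, U_y = x$U_y,
                 p_value = x$p_two_sided,
                 n_x = x$n_x, n_y = x$n_y, method = x$method)
}

#' Summarise held durations per feedback condition
#'
#' Box-plot style summaries of session durations for each condition:
#' median and quartiles (linear interpolation), outliers by the
#' `1.5 * IQR` rule, and a rank-sum test of every condition against the
#' reference (no-feedback) condition.
#'
#' @param records Tibble with one session per row; must contain `condition`
#'   and the duration column.
#' @param reference Condition the others are tested against (no test row
#'   for the reference itself). Ignored when only one condition is present.
#' @param duration_col Name of the duration column.
#' @param plot_data_path Optional path; when given, the per-session plot
#'   data (condition, duration) is written there as CSV.
#' @return A `condition_summary` tibble: `condition`, `n`, `median_s`,
#'   `q1_s`, `q3_s`, `outliers` (list-column), `U`, `p_value`. The input
#'   records are attached as attribute `records` for plotting.
#' @export
summarize_conditions <- function(records, reference = "NFB",
                                 duration_col = "duration_s",
                                 plot_data_path = NULL) {
  if (!"condition" %in% names(records)) {
    stop("`records` must have a `condition` column", call. = FALSE)
  }
  if (!duration_col %in% names(records)) {
    stop("`records` must have a `", duration_col, "` column", call. = FALSE)
  }
  if (anyNA(records$condition)) {
    stop("missing condition labels", call. = FALSE)
  }
  dur <- records[[duration_col]]
  conds <- unique(records$condition)

  summ <- purrr::map_dfr(conds, function(cond) {
    d <- dur[records$condition == cond]
    q <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    out <- d[d < q[1] - 1.5 * iqr | d > q[3] + 1.5 * iqr]
    tibble::tibble(condition = cond, n = length(d),
                   median_s = q[2], q1_s = q[1], q3_s = q[3],
                   outliers = list(sort(out)))
  })

  if (length(conds) > 1L && reference %in% conds) {
    ref <- dur[records$condition == reference]
    tests <- purrr::map_dfr(summ$condition, function(cond) {
      if (cond == reference) {
        return(tibble::tibble(U = NA_real_, p_value = NA_real_))
      }
      tt <- mann_whitney_u(dur[records$condition == cond], ref)
      tibble::tibble(U = tt$U, p_value = tt$p_two_sided)
    })
    summ <- dplyr::bind_cols(summ, tests)
  } else {
    summ$U <- NA_real_
    summ$p_value <- NA_real_
  }

  if (!is.null(plot_data_path)) {
    utils::write.csv(
      data.frame(condition = records$condition, duration_s = dur),
      plot_data_path, row.names = FALSE)
  }
  structure(summ, records = tibble::tibble(condition = records$condition,
                                           duration_s = dur),
            class = c("condition_summary", class(summ)))
}

#' Box plot of per-condition durations
#'
#' @param object A `condition_summary` from [summarize_conditions()].
#' @param ... Unused.
#' @return A ggplot object; diamonds mark outlier scores.
#' @exportS3Method ggplot2::autoplot
autoplot.condition_summary <- function(object, ...) {
  df <- attr(object, "records")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$duration_s)) +
    ggplot2::geom_boxplot(outlier.shape = 18, outlier.size = 3) +
    ggplot2::labs(x = "feedback condition", y = "time in correct stance (s)")
}

#' Write / read a frame as a PGM heat map
#'
#' Exports a filtered frame as a plain-text portable graymap (P2), one
#' gray level per cell, `maxval = 2^bit_depth - 1`, row-major — the file
#' form of the heat maps used to inspect stance pressure distributions.
#' The round trip through [read_pgm()] is lossless.
#'
#' @param frame A filtered [pressure_frame()].
#' @param path Output path.
#' @param config A [sensor_config()].
#' @return `render_heatmap()` returns `path` invisibly; `read_pgm()`
#'   returns the integer matrix stored in the file.
#' @export
render_heatmap <- function(frame, path, config = sensor_config()) {
  m <- unclass(frame)
  lines <- c(
    "P2",
    sprintf("%d %d", ncol(m), nrow(m)),
    sprintf("%d", config$max_raw),
    apply(m, 1L, paste, collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname render_heatmap
#' @export
read_pgm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (trimws(lines[1]) != "P2") stop("not a plain (P2) PGM file", call. = FALSE)
  tokens <- scan(text = paste(lines[-1], collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  if (any(px < 0 | px > maxval)) stop("PGM pixel out of range", call. = FALSE)
  matrix(as.integer(px), nrow = h, ncol = w, byrow = TRUE)
}
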