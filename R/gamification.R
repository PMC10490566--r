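#' Level reached for a held duration
#'
#' Practitioners start at Level 0 and ascend one level for every 10 seconds
#' of correctly held stance, so `level = floor(duration_s / 10)`. Exactly
#' 10.0 s awards Level 1.
#'
#' @param duration_s Held duration(s) in seconds, `>= 0`.
#' @return Integer level(s).
#' @examples
#' level_for_duration(c(0, 10, 65))  # 0 1 6
#' @export
level_for_duration <- function(duration_s) {
  if (any(duration_s < 0)) stop("duration must be >= 0", call. = FALSE)
  as.integer(floor(duration_s / 10))
}

#' Skill group for a level
#'
#' Levels are grouped by recommended stance-holding durations: beginner
#' (Levels 0-6), intermediate (7-12), veteran (13-18) and expert (19 and
#' onwards).
#'
#' @param level Integer level(s), `>= 0`.
#' @return Character group(s).
#' @examples
#' group_for_level(c(6, 13, 19))
#' @export
group_for_level <- function(level) {
  if (any(level < 0)) stop("level must be >= 0", call. = FALSE)
  ifelse(level <= 6, "beginner",
  ifelse(level <= 12, "intermediate",
  ifelse(level <= 18, "veteran", "expert")))
}

#' Update the leaderboard with a completed session
#'
#' Inserts a completed session and re-ranks the board by total held
#' duration, longest first; ties rank the earlier recording higher. A
#' returning participant keeps only their best (longest) session.
#'
#' @param board A leaderboard tibble (possibly empty / `NULL`) with columns
#'   `participant_id`, `total_duration_s`, `final_level`, `group`, `rank`,
#'   `recorded_at`.
#' @param record A completed (`BROKEN`) `session_record`, or a list with
#'   `participant_id`, `good_duration_s` and optionally `recorded_at`.
#' @param recorded_at Timestamp of the entry (seconds or any orderable
#'   scalar); defaults to one past the latest on the board.
#' @return The re-ranked leaderboard tibble.
#' @export
update_leaderboard <- function(board, record, recorded_at = NULL) {
  if (is.null(board) || !nrow(board)) board <- empty_leaderboard()
  if (inherits(record, "session_record")) {
    if (record$phase != "BROKEN") {
      stop("only completed (BROKEN) sessions enter the leaderboard",
           call. = FALSE)
    }
    dur <- record$good_duration_s
    pid <- record$participant_id
  } else {
    dur <- record$good_duration_s
    pid <- record$participant_id
    recorded_at <- recorded_at %||% record$recorded_at
  }
  recorded_at <- recorded_at %||%
    (if (nrow(board)) max(board$recorded_at) + 1 else 1)
  lvl <- level_for_duration(dur)
  entry <- tibble::tibble(
    participant_id = pid,
    total_duration_s = dur,
    final_level = lvl,
    group = group_for_level(lvl),
    rank = NA_integer_,
    recorded_at = as.numeric(recorded_at)
  )
  board <- dplyr::bind_rows(board, entry)
  board <- board |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(dplyr::desc(.data$total_duration_s), .data$recorded_at,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$total_duration_s), .data$recorded_at) |>
    dplyr::mutate(rank = dplyr::row_number())
  board
}

empty_leaderboard <- function() {
  tibble::tibble(
    participant_id = character(), total_duration_s = numeric(),
    final_level = integer(), group = character(), rank = integer(),
    recorded_at = numeric()
  )
}

#' Read / write the leaderboard as JSON
#'
#' @param board A leaderboard tibble.
#' @param path JSON file path.
#' @return `read_leaderboard()` returns the leaderboard tibble (empty when
#'   the file does not exist); `write_leaderboard()` returns `path`
#'   invisibly.
#' @export
write_leaderboard <- function(board, path) {
  jsonlite::write_json(board, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_leaderboard
#' @export
read_leaderboard <- function(path) {
  if (!file.exists(path)) return(empty_leaderboard())
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(df)) return(empty_leaderboard())
  tibble::as_tibble(df) |>
    dplyr::mutate(final_level = as.integer(.data$final_level),
                  rank = as.integer(.data$rank),
                  recorded_at = as.numeric(.data$recorded_at))
}
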