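#' Session schedules
#'
#' A session schedule records when each of the repeated within-day test
#' sessions started, in minutes from the start of the first session. All
#' pairwise session classification results are tagged with the elapsed time
#' between the two sessions, and those durations drive the grouping into the
#' time intervals T1-T4.
#'
#' @param session_ids character vector of session labels, e.g. `c("S1","S2")`.
#' @param start_min numeric vector of session start times in minutes from the
#'   first session; must be strictly increasing and start at 0.
#' @return An object of class `session_schedule`: a data frame with columns
#'   `session` and `start_min`.
#' @examples
#' session_schedule(paste0("S", 1:3), c(0, 10, 40))
#' @export
session_schedule <- function(session_ids, start_min) {
  if (length(session_ids) != length(start_min))
    stop("session_ids and start_min must have the same length")
  if (length(start_min) < 1L || any(!is.finite(start_min)))
    stop("start_min must be finite")
  if (any(diff(start_min) <= 0))
    stop("start_min must be strictly increasing")
  out <- data.frame(session = as.character(session_ids),
                    start_min = as.numeric(start_min),
                    stringsAsFactors = FALSE)
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' Default six-session within-day schedule
#'
#' Six sessions in one day with 10-minute rests after the first, third and
#' fifth session, a 30-minute rest between the second and third, and a
#' 90-minute rest between the fourth and fifth. Start times are therefore
#' 0, 10, 40, 50, 140 and 150 minutes, giving pairwise durations from 10 to
#' 150 minutes.
#'
#' @return A [session_schedule()] for sessions S1-S6.
#' @examples
#' default_schedule()
#' session_duration(default_schedule(), "S1", "S6")  # 150
#' @export
default_schedule <- function() {
  session_schedule(paste0("S", 1:6), c(0, 10, 40, 50, 140, 150))
}

#' Elapsed time between two sessions
#'
#' @param schedule a [session_schedule()].
#' @param si,sj session labels present in the schedule.
#' @return Elapsed time in minutes (non-negative).
#' @export
session_duration <- function(schedule, si, sj) {
  idx <- match(c(si, sj), schedule$session)
  if (anyNA(idx)) stop("unknown session label")
  abs(schedule$start_min[idx[2]] - schedule$start_min[idx[1]])
}

#' All pairwise session durations
#'
#' @param schedule a [session_schedule()].
#' @return Data frame with one row per unordered session pair: columns
#'   `session_i`, `session_j`, `duration_min`.
#' @export
session_pairs <- function(schedule) {
  k <- nrow(schedule)
  if (k < 2L) stop("need at least two sessions")
  ij <- utils::combn(k, 2)
  data.frame(
    session_i = schedule$session[ij[1, ]],
    session_j = schedule$session[ij[2, ]],
    duration_min = schedule$start_min[ij[2, ]] - schedule$start_min[ij[1, ]],
    stringsAsFactors = FALSE
  )
}

#' Read and write schedule CSV files
#'
#' The on-disk layout is a two-column CSV with header `session,start_min`.
#'
#' @param schedule a [session_schedule()].
#' @param path file path.
#' @return `read_schedule_csv` returns a [session_schedule()];
#'   `write_schedule_csv` returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  session_schedule(df$session, df$start_min)
}
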