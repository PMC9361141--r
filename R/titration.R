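#' Recommended bedtime from last week's sleep
#'
#' The core of sleep-restriction therapy: the prescribed bed window is
#' matched to how long the participant actually sleeps. The recommended
#' bedtime is found by subtracting last week's mean total sleep time plus a
#' 30-minute buffer from the desired wake-up time, on the 24 h circle.
#'
#' @param desired_wake Desired wake-up time (`"HH:MM"` or minutes).
#' @param prior_mean_tst Last week's mean total sleep time in minutes
#'   (> 0). `NA` signals a missing weekly summary and is an error; callers
#'   should carry the previous schedule forward instead.
#' @param buffer Minutes added on top of mean sleep time (default 30).
#' @return The recommended bedtime as minutes since midnight.
#' @examples
#' format_clock(recommend_bedtime("06:30", 390))  # "23:30"
#' @export
recommend_bedtime <- function(desired_wake, prior_mean_tst, buffer = 30L) {
  if (length(prior_mean_tst) != 1 || is.na(prior_mean_tst)) {
    stop("no usable weekly summary: carry the current schedule forward",
         call. = FALSE)
  }
  if (prior_mean_tst <= 0) {
    stop("prior mean total sleep time must be positive", call. = FALSE)
  }
  clock_time(clock_time(desired_wake) - round(prior_mean_tst + buffer))
}

#' Weekly time-in-bed adjustment from sleep efficiency
#'
#' The titration rule: a week averaging over 90% sleep efficiency earns 15
#' minutes of extra time in bed, 85%-90% (both ends inclusive) keeps the
#' window unchanged, and below 85% the window is restricted by a further 15
#' minutes.
#'
#' @param weekly_se Mean sleep efficiency for the week, percent in
#'   `[0, 100]`.
#' @return `+15`, `0`, or `-15` (minutes), vectorized over `weekly_se`.
#' @examples
#' adjust_time_in_bed(c(95, 90, 87, 85, 80))
#' @export
adjust_time_in_bed <- function(weekly_se) {
  if (any(is.na(weekly_se)) || any(weekly_se < 0 | weekly_se > 100)) {
    stop("weekly sleep efficiency must be in [0, 100]", call. = FALSE)
  }
  ifelse(weekly_se > 90, 15L, ifelse(weekly_se < 85, -15L, 0L))
}

#' Construct a weekly sleep schedule
#'
#' @param participant_id Participant identifier.
#' @param week_index Program week the schedule applies to (2..4; restriction
#'   is inactive in week 1).
#' @param desired_wake Desired wake-up time.
#' @param recommended_bed Recommended bedtime (from [recommend_bedtime()]).
#' @param set_bed Bedtime the participant actually set (defaults to the
#'   recommendation).
#' @param floor_tib,cap_tib Safety bounds on the prescribed bed window,
#'   minutes (defaults 300 and 600). The floor is the conventional 5 h
#'   minimum of sleep-restriction therapy; the cap rejects degenerate
#'   inputs.
#' @return A one-row tibble with the schedule fields, including the
#'   prescribed time in bed implied by `set_bed` and `desired_wake`.
#' @export
sleep_schedule <- function(participant_id, week_index, desired_wake,
                           recommended_bed, set_bed = recommended_bed,
                           floor_tib = 300L, cap_tib = 600L) {
  stopifnot(length(week_index) == 1, week_index %in% 2:4)
  desired_wake <- clock_time(desired_wake)
  recommended_bed <- clock_time(recommended_bed)
  set_bed <- clock_time(set_bed)
  tib <- clock_diff(set_bed, desired_wake)
  if (tib < floor_tib || tib > cap_tib) {
    stop("prescribed time in bed (", tib, " min) outside the allowed ",
         "window [", floor_tib, ", ", cap_tib, "] min", call. = FALSE)
  }
  tibble::tibble(
    participant_id = as.character(participant_id),
    week_index = as.integer(week_index),
    desired_wake_time = desired_wake,
    recommended_bed_time = recommended_bed,
    set_bed_time = set_bed,
    prescribed_time_in_bed = as.integer(tib)
  )
}

#' Titrate next week's sleep schedule
#'
#' Composes the weekly titration step performed at the end of each program
#' week (active weeks 2-4): the time-in-bed adjustment earned by the week's
#' mean sleep efficiency is applied to the current prescribed window,
#' clamped to the safety floor and cap, and the bedtime is recomputed from
#' the anchored desired wake time. The wake time is the user's anchor; the
#' adjustment always moves the bedtime. A non-adherent week (too few diary
#' days) carries the current schedule forward unchanged apart from the week
#' index.
#'
#' @param summary A weekly summary from [summarize_week()].
#' @param desired_wake Desired wake-up time for next week.
#' @param current The current schedule row ([sleep_schedule()]); `NULL` when
#'   titrating for the first time (week 2), in which case the bedtime comes
#'   from [recommend_bedtime()] on the summary's mean sleep time.
#' @param floor_tib,cap_tib Safety bounds, as in [sleep_schedule()].
#' @return A one-row schedule tibble for `summary$week_index + 1`.
#' @export
schedule_next_week <- function(summary, desired_wake, current = NULL,
                               floor_tib = 300L, cap_tib = 600L) {
  next_week <- summary$week_index + 1L
  stopifnot(next_week %in% 2:4)
  desired_wake <- clock_time(desired_wake)

  if (!summary$adherent) {
    if (is.null(current)) {
      stop("non-adherent week with no prior schedule to carry forward",
           call. = FALSE)
    }
    out <- current
    out$week_index <- next_week
    return(out)
  }

  recommended <- recommend_bedtime(desired_wake, summary$mean_total_sleep_time)
  if (is.null(current)) {
    # first titration: bed window straight from last week's sleep + buffer
    tib <- clock_diff(recommended, desired_wake)
  } else {
    delta <- adjust_time_in_bed(summary$mean_sleep_efficiency)
    tib <- current$prescribed_time_in_bed + delta
  }
  tib <- min(max(tib, floor_tib), cap_tib)
  sleep_schedule(summary$participant_id, next_week, desired_wake,
                 recommended_bed = recommended,
                 set_bed = clock_time(desired_wake - tib),
                 floor_tib = floor_tib, cap_tib = cap_tib)
}

#' Read and write weekly sleep schedules
#'
#' CSV with one row per participant-week, clock times as `"HH:MM"`.
#'
#' @param schedules A schedule table ([sleep_schedule()] rows).
#' @param path File path (`.csv` or `.json`).
#' @return `read_schedules()` returns a tibble; `write_schedules()` returns
#'   `path` invisibly.
#' @export
write_schedules <- function(schedules, path) {
  out <- schedules
  for (col in c("desired_wake_time", "recommended_bed_time", "set_bed_time")) {
    out[[col]] <- format_clock(out[[col]])
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_schedules
#' @export
read_schedules <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    raw <- tibble::as_tibble(
      utils::read.csv(path, stringsAsFactors = FALSE,
                      colClasses = c(participant_id = "character"))
    )
  }
  for (col in c("desired_wake_time", "recommended_bed_time", "set_bed_time")) {
    raw[[col]] <- clock_time(raw[[col]])
  }
  raw$week_index <- as.integer(raw$week_index)
  raw$prescribed_time_in_bed <- as.integer(raw$prescribed_time_in_bed)
  raw
}
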