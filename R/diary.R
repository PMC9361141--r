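#' Construct a validated sleep-diary entry
#'
#' One row per participant-night, holding the ten items a participant records
#' each morning: when they got into bed, how long it took to fall asleep
#' (sleep-onset latency, SOL), the number and total duration of nocturnal
#' awakenings (wake after sleep onset, WASO), the time of final awakening,
#' how long they lay in bed afterwards (bed-out latency), nap duration,
#' times of excessive daytime sleepiness, pre-bed behaviors, and whether the
#' date was a holiday.
#'
#' Validation is strict: a missing required field invalidates the entry
#' rather than being imputed as zero, entries whose latencies exceed the
#' bed interval (which would imply negative sleep) are rejected, and a
#' reported awakening duration with zero awakenings is inconsistent.
#'
#' @param participant_id Participant identifier (scalar character).
#' @param date Calendar date (`Date` or ISO-8601 string).
#' @param bed_time Time of getting into bed (`"HH:MM"` or minutes).
#' @param sleep_onset_latency Minutes from bed to sleep onset, >= 0.
#' @param n_awakenings Count of nocturnal awakenings, >= 0.
#' @param awakening_duration Total minutes awake after sleep onset, >= 0.
#' @param final_awakening_time Time of final awakening.
#' @param bed_out_latency Minutes from final awakening to arising, >= 0.
#' @param nap_duration Daytime nap minutes, >= 0 (recorded, not used in
#'   the bed-interval formulas).
#' @param sleepiness_times Times of excessive daytime sleepiness: a vector
#'   accepted by [clock_time()] (possibly empty). Stored as state only.
#' @param alcohol,caffeine,smoking,hypnotic_use Pre-bed behavior flags.
#' @param is_holiday Whether the date was a holiday.
#' @return A one-row [tibble::tibble()] with class `"diary_entry"` columns.
#' @seealso [time_in_bed()], [total_sleep_time()], [sleep_efficiency()]
#' @examples
#' e <- diary_entry("p01", "2021-01-04", bed_time = "23:30",
#'                  sleep_onset_latency = 20, n_awakenings = 1,
#'                  awakening_duration = 25, final_awakening_time = "06:45",
#'                  bed_out_latency = 15)
#' time_in_bed(e)       # 450
#' total_sleep_time(e)  # 390
#' @export
diary_entry <- function(participant_id, date, bed_time,
                        sleep_onset_latency, n_awakenings,
                        awakening_duration, final_awakening_time,
                        bed_out_latency, nap_duration = 0,
                        sleepiness_times = integer(0),
                        alcohol = FALSE, caffeine = FALSE, smoking = FALSE,
                        hypnotic_use = FALSE, is_holiday = FALSE) {
  entry <- tibble::tibble(
    participant_id = as.character(participant_id),
    date = as.Date(date),
    is_holiday = as.logical(is_holiday),
    bed_time = clock_time(bed_time),
    sleep_onset_latency = as.integer(sleep_onset_latency),
    n_awakenings = as.integer(n_awakenings),
    awakening_duration = as.integer(awakening_duration),
    final_awakening_time = clock_time(final_awakening_time),
    bed_out_latency = as.integer(bed_out_latency),
    nap_duration = as.integer(nap_duration),
    sleepiness_times = list(clock_time(sleepiness_times)),
    alcohol = as.logical(alcohol),
    caffeine = as.logical(caffeine),
    smoking = as.logical(smoking),
    hypnotic_use = as.logical(hypnotic_use)
  )
  validate_diary(entry)
}

diary_columns <- c(
  "participant_id", "date", "is_holiday", "bed_time",
  "sleep_onset_latency", "n_awakenings", "awakening_duration",
  "final_awakening_time", "bed_out_latency", "nap_duration",
  "sleepiness_times", "alcohol", "caffeine", "smoking", "hypnotic_use"
)

#' Validate a table of diary entries
#'
#' Checks the structural invariants of the diary schema: required fields
#' present and non-missing, non-negative durations, no awakening minutes
#' without awakenings, a strictly positive bed interval, and latencies that
#' fit inside it (so total sleep time is never negative).
#'
#' @param entries A data frame of diary rows (as built by [diary_entry()]
#'   or read by [read_diary()]).
#' @return The validated entries, invisibly coerced to a tibble.
#' @export
validate_diary <- function(entries) {
  entries <- tibble::as_tibble(entries)
  missing_cols <- setdiff(diary_columns, names(entries))
  if (length(missing_cols)) {
    stop("diary is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries <- entries[diary_columns]
  required <- setdiff(diary_columns, "sleepiness_times")
  for (col in required) {
    if (anyNA(entries[[col]])) {
      stop("diary column '", col, "' has missing values; ",
           "entries with missing items are invalid", call. = FALSE)
    }
  }
  dur <- c("sleep_onset_latency", "n_awakenings", "awakening_duration",
           "bed_out_latency", "nap_duration")
  for (col in dur) {
    if (any(entries[[col]] < 0)) {
      stop("diary column '", col, "' must be non-negative", call. = FALSE)
    }
  }
  bad <- entries$n_awakenings == 0 & entries$awakening_duration > 0
  if (any(bad)) {
    stop("awakening_duration > 0 with n_awakenings = 0 on ",
         sum(bad), " entr", if (sum(bad) == 1) "y" else "ies", call. = FALSE)
  }
  tib <- time_in_bed(entries)  # errors on zero-length intervals
  waste <- entries$sleep_onset_latency + entries$awakening_duration +
    entries$bed_out_latency
  if (any(waste > tib)) {
    stop("latencies exceed time in bed (negative total sleep time) on ",
         sum(waste > tib), " entr",
         if (sum(waste > tib) == 1) "y" else "ies", call. = FALSE)
  }
  entries
}

#' Time in bed
#'
#' Final arising time minus time of getting into bed, in minutes. The final
#' arising time is the final awakening time plus the bed-out latency. When
#' the arising clock is at or before the bed clock the interval wraps
#' midnight; an interval of exactly zero minutes is rejected because every
#' downstream quantity divides by it.
#'
#' @param entries A data frame of diary rows.
#' @return Integer minutes in `(0, 1440)`, one per entry.
#' @export
time_in_bed <- function(entries) {
  arising <- (entries$final_awakening_time + entries$bed_out_latency) %% 1440L
  tib <- clock_diff(entries$bed_time, arising)
  if (any(tib == 0)) {
    stop("zero-length bed interval (arising time equals bedtime) on ",
         sum(tib == 0), " entr",
         if (sum(tib == 0) == 1) "y" else "ies", call. = FALSE)
  }
  tib
}

#' Total sleep time
#'
#' Time in bed minus sleep-onset latency, wake after sleep onset, and
#' bed-out latency. A negative result means the diary is internally
#' inconsistent and is rejected.
#'
#' @inheritParams time_in_bed
#' @return Integer minutes >= 0, one per entry.
#' @export
total_sleep_time <- function(entries) {
  tst <- time_in_bed(entries) - entries$sleep_onset_latency -
    entries$awakening_duration - entries$bed_out_latency
  if (any(tst < 0)) {
    stop("negative total sleep time: latencies exceed time in bed",
         call. = FALSE)
  }
  as.integer(tst)
}

#' Sleep efficiency
#'
#' `100 * total sleep time / time in bed`, as a percentage in `[0, 100]`.
#' Full precision is kept internally; presentation layers round to one
#' decimal place.
#'
#' @inheritParams time_in_bed
#' @return Numeric percent in `[0, 100]`, one per entry.
#' @export
sleep_efficiency <- function(entries) {
  100 * total_sleep_time(entries) / time_in_bed(entries)
}

#' Derived sleep variables for each diary entry
#'
#' @inheritParams time_in_bed
#' @return A tibble with `participant_id`, `date`, `time_in_bed`,
#'   `total_sleep_time`, and `sleep_efficiency` columns.
#' @export
daily_metrics <- function(entries) {
  entries <- validate_diary(entries)
  tibble::tibble(
    participant_id = entries$participant_id,
    date = entries$date,
    time_in_bed = time_in_bed(entries),
    total_sleep_time = total_sleep_time(entries),
    sleep_efficiency = sleep_efficiency(entries)
  )
}

#' Weekly diary summary
#'
#' Aggregates one participant's diary entries for one 7-day program week
#' into the quantities the sleep-restriction titration consumes: the mean
#' total sleep time and mean sleep efficiency over the days actually
#' recorded. A week with fewer than `min_entries` recorded days is flagged
#' non-adherent; the titration then carries the previous schedule forward
#' instead of retitrating on an unreliable mean.
#'
#' @param entries Diary rows from a single participant and week (possibly
#'   zero rows).
#' @param week_index Program week, 1..4.
#' @param min_entries Minimum recorded days for a usable weekly mean
#'   (default 3).
#' @return A one-row tibble: `participant_id`, `week_index`, `n_entries`,
#'   `mean_total_sleep_time`, `mean_sleep_efficiency`, `adherent`. Means are
#'   `NA` when no entries exist.
#' @export
summarize_week <- function(entries, week_index, min_entries = 3L) {
  stopifnot(length(week_index) == 1, week_index %in% 1:4)
  n <- nrow(entries)
  if (is.null(n)) n <- 0L
  if (n == 0) {
    return(tibble::tibble(
      participant_id = NA_character_, week_index = as.integer(week_index),
      n_entries = 0L, mean_total_sleep_time = NA_real_,
      mean_sleep_efficiency = NA_real_, adherent = FALSE
    ))
  }
  if (n > 7) {
    stop("a program week has at most 7 diary entries, got ", n, call. = FALSE)
  }
  entries <- validate_diary(entries)
  pid <- unique(entries$participant_id)
  if (length(pid) != 1) {
    stop("summarize_week expects entries from a single participant",
         call. = FALSE)
  }
  tibble::tibble(
    participant_id = pid,
    week_index = as.integer(week_index),
    n_entries = as.integer(n),
    mean_total_sleep_time = mean(total_sleep_time(entries)),
    mean_sleep_efficiency = mean(sleep_efficiency(entries)),
    adherent = n >= min_entries
  )
}

#' Read and write sleep diaries
#'
#' CSV with one row per participant-day: clock times as `"HH:MM"`, dates as
#' ISO-8601, behavior flags as logicals, and `sleepiness_times` as a
#' semicolon-joined list of `"HH:MM"` times (empty for none). `read_diary()`
#' also accepts a JSON mirror of the same schema (records orientation);
#' the format is chosen by file extension.
#'
#' @param path File path (`.csv` or `.json`).
#' @param entries A diary table to write.
#' @return `read_diary()` returns a validated diary tibble; `write_diary()`
#'   returns `path` invisibly.
#' @export
read_diary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    raw <- tibble::as_tibble(raw)
    if (!is.list(raw$sleepiness_times)) {
      raw$sleepiness_times <- as.list(raw$sleepiness_times)
    }
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(participant_id = "character"))
    raw <- tibble::as_tibble(raw)
    raw$sleepiness_times <- lapply(
      strsplit(ifelse(is.na(raw$sleepiness_times), "",
                      as.character(raw$sleepiness_times)), ";"),
      function(x) x[nzchar(x)]
    )
  }
  raw$date <- as.Date(raw$date)
  for (col in c("bed_time", "final_awakening_time")) {
    raw[[col]] <- clock_time(raw[[col]])
  }
  raw$sleepiness_times <- lapply(raw$sleepiness_times, clock_time)
  validate_diary(raw)
}

#' @rdname read_diary
#' @export
write_diary <- function(entries, path) {
  entries <- validate_diary(entries)
  out <- entries
  out$bed_time <- format_clock(out$bed_time)
  out$final_awakening_time <- format_clock(out$final_awakening_time)
  out$date <- format(out$date, "%Y-%m-%d")
  stimes <- vapply(out$sleepiness_times,
                   function(x) paste(format_clock(x), collapse = ";"), "")
  out$sleepiness_times <- stimes
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out$sleepiness_times <- lapply(entries$sleepiness_times, format_clock)
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
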