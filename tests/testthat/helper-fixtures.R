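# A valid diary entry with overridable fields: bed 23:30, asleep 23:50,
# one 25-min awakening, final awakening 06:45, up at 07:00 (TIB 450,
# TST 390, SE 86.7%).
make_entry <- function(participant_id = "p01", date = "2021-01-04",
                       bed_time = "23:30", sleep_onset_latency = 20,
                       n_awakenings = 1, awakening_duration = 25,
                       final_awakening_time = "06:45", bed_out_latency = 15,
                       ...) {
  diary_entry(participant_id, date, bed_time, sleep_onset_latency,
              n_awakenings, awakening_duration, final_awakening_time,
              bed_out_latency, ...)
}

# n copies of make_entry on consecutive dates
make_week <- function(n = 7, start = "2021-01-04", ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_entry(date = as.Date(start) + i - 1, ...)
  }))
}

# minimal in-code catalog: one message per category
tiny_catalog <- function() {
  tibble::tibble(
    message_id = c("m-dia", "m-pra", "m-hyg", "m-stc", "m-res"),
    category = c("diary_feedback", "praise", "hygiene",
                 "stimulus_control", "restriction"),
    topic = c("diary", "adherence", "caffeine", "bed_association",
              "schedule"),
    slots = list("after_waking", "around_noon",
                 c("evening", "around_noon"), "before_bedtime",
                 "before_bedtime"),
    priority = c(5L, 6L, 3L, 4L, 5L),
    condition = list(
      NULL,
      list(field = "adherence_streak", op = "ge", value = 3),
      list(field = "caffeine", op = "is_true"),
      NULL, NULL
    ),
    text = paste("text", 1:5)
  )
}

make_state <- function(study_day = 10, adherence_streak = 0,
                       habits = list(caffeine = FALSE), ...) {
  participant_state("p01", "female", 35, 12, habits = habits,
                    study_day = study_day,
                    adherence_streak = adherence_streak, ...)
}
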