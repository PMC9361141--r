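#' Participant state for prompt selection
#'
#' The snapshot of one participant the prompt engine sees when it selects a
#' message: demographics, the latest insomnia severity score, lifestyle
#' habit flags, the self-declared receptive time windows, diary history,
#' the current sleep schedule, the program day, and the current run of
#' consecutive diary days.
#'
#' @param participant_id Identifier.
#' @param sex `"female"` or `"male"`.
#' @param age Years.
#' @param current_isi Latest ISI total (0-28).
#' @param habits Named logical vector/list of lifestyle flags (e.g.
#'   `caffeine`, `alcohol`, `smoking`, `hypnotic_use`).
#' @param receptive_windows Two-column matrix or data frame of
#'   `(start, end)` clock times during which the participant is receptive
#'   to prompts; zero rows means no preference. Windows must not overlap.
#' @param diary_history Diary tibble (possibly empty) of entries so far.
#' @param schedule Current [sleep_schedule()] row, or `NULL` in week 1.
#' @param study_day Program day, 1..28.
#' @param adherence_streak Consecutive diary days up to yesterday.
#' @return A list of class `"participant_state"`.
#' @export
participant_state <- function(participant_id, sex, age, current_isi,
                              habits = list(), receptive_windows = NULL,
                              diary_history = NULL, schedule = NULL,
                              study_day = 1L, adherence_streak = 0L) {
  stopifnot(study_day >= 1, study_day <= 28)
  if (!is.null(receptive_windows)) {
    rw <- as.data.frame(receptive_windows)
    names(rw) <- c("start", "end")
    rw$start <- clock_time(rw$start)
    rw$end <- clock_time(rw$end)
    if (nrow(rw) > 1) {
      o <- order(rw$start)
      if (any(rw$end[o][-nrow(rw)] > rw$start[o][-1])) {
        stop("receptive windows must not overlap", call. = FALSE)
      }
    }
    receptive_windows <- rw
  }
  structure(list(
    participant_id = as.character(participant_id), sex = sex,
    age = as.integer(age), current_isi = as.integer(current_isi),
    habits = habits, receptive_windows = receptive_windows,
    diary_history = diary_history, schedule = schedule,
    study_day = as.integer(study_day),
    adherence_streak = as.integer(adherence_streak)
  ), class = "participant_state")
}

#' Flatten participant state into predicate fields
#'
#' Produces the flat named list of scalar fields the rule language can
#' reference: demographics (`age`, `sex`), `current_isi`, `study_day`,
#' `study_week`, `adherence_streak`, each habit flag by name, and diary
#' derived values — `last_se`, `last_tst`, `last_tib`, `last_sol`,
#' `last_nap`, `n_diary_entries` — computed from the most recent entry,
#' `NA` when no diary exists yet.
#'
#' @param state A [participant_state()].
#' @return A named list of scalars.
#' @export
state_fields <- function(state) {
  fields <- list(
    age = state$age, sex = state$sex, current_isi = state$current_isi,
    study_day = state$study_day,
    study_week = ((state$study_day - 1L) %/% 7L) + 1L,
    adherence_streak = state$adherence_streak,
    last_se = NA_real_, last_tst = NA_real_, last_tib = NA_real_,
    last_sol = NA_real_, last_nap = NA_real_,
    n_diary_entries = 0L,
    prescribed_tib = if (is.null(state$schedule)) NA_real_
                     else state$schedule$prescribed_time_in_bed
  )
  for (h in names(state$habits)) fields[[h]] <- isTRUE(state$habits[[h]])
  dh <- state$diary_history
  if (!is.null(dh) && nrow(dh) > 0) {
    last <- dh[which.max(dh$date), ]
    fields$last_se <- sleep_efficiency(last)
    fields$last_tst <- total_sleep_time(last)
    fields$last_tib <- time_in_bed(last)
    fields$last_sol <- last$sleep_onset_latency
    fields$last_nap <- last$nap_duration
    fields$n_diary_entries <- nrow(dh)
  }
  fields
}

#' Evaluate a declarative prompt rule
#'
#' Rules are small, side-effect-free predicate trees serialized with the
#' catalog — no code execution. A leaf is
#' `list(field = , op = , value = )` with operators `eq`, `ne`, `lt`, `le`,
#' `gt`, `ge`, `in`, `is_true`, `is_false`; comparisons against a missing
#' field value are false (never an error). Combinators are `list(all = )`,
#' `list(any = )`, and `list(not = )`; the empty rule (or `NULL`) is always
#' true.
#'
#' @param rule A rule node (parsed from the catalog's JSON `condition`).
#' @param fields Flat field list from [state_fields()].
#' @return `TRUE` or `FALSE`.
#' @export
eval_rule <- function(rule, fields) {
  if (is.null(rule) || length(rule) == 0) return(TRUE)
  if (!is.null(rule$all)) {
    return(all(vapply(rule$all, eval_rule, logical(1), fields = fields)))
  }
  if (!is.null(rule$any)) {
    return(any(vapply(rule$any, eval_rule, logical(1), fields = fields)))
  }
  if (!is.null(rule$not)) return(!eval_rule(rule$not, fields))
  if (is.null(rule$field) || is.null(rule$op)) {
    stop("malformed rule node: needs 'field' and 'op' (or a combinator)",
         call. = FALSE)
  }
  x <- fields[[rule$field]]
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(FALSE)
  v <- rule$value
  switch(rule$op,
    eq = isTRUE(x == v), ne = isTRUE(x != v),
    lt = isTRUE(x < v), le = isTRUE(x <= v),
    gt = isTRUE(x > v), ge = isTRUE(x >= v),
    `in` = x %in% unlist(v),
    is_true = isTRUE(x), is_false = identical(x, FALSE),
    stop("unknown rule operator '", rule$op, "'", call. = FALSE)
  )
}

prompt_categories <- c("diary_feedback", "praise", "hygiene",
                       "stimulus_control", "restriction")
prompt_slots <- c("after_waking", "around_noon", "evening", "before_bedtime")

#' Is a message category active in a given program week?
#'
#' Phase gating of the program's therapy components: diary feedback, praise,
#' and sleep-hygiene education run for all four weeks; stimulus-control and
#' sleep-restriction content starts in week 2.
#'
#' @param category One of `"diary_feedback"`, `"praise"`, `"hygiene"`,
#'   `"stimulus_control"`, `"restriction"`.
#' @param study_week Program week, 1..4.
#' @return Logical, vectorized over `category`.
#' @export
phase_active <- function(category, study_week) {
  stopifnot(all(study_week %in% 1:4))
  bad <- !category %in% prompt_categories
  if (any(bad)) {
    stop("unknown prompt category: ", paste(unique(category[bad]),
         collapse = ", "), call. = FALSE)
  }
  start_week <- ifelse(category %in% c("stimulus_control", "restriction"),
                       2L, 1L)
  study_week >= start_week
}

#' Messages eligible for one participant, slot, and day
#'
#' A catalog message is eligible when the slot matches one of its delivery
#' slots, its category's program phase is active in the participant's
#' current week, and its firing condition evaluates true on the
#' participant's state.
#'
#' @param catalog A catalog tibble ([read_catalog()] / [default_catalog()]).
#' @param state A [participant_state()].
#' @param slot One of the four delivery slots.
#' @return The eligible subset of `catalog` rows (possibly zero rows).
#' @export
eligible_messages <- function(catalog, state, slot) {
  stopifnot(slot %in% prompt_slots)
  if (nrow(catalog) == 0) return(catalog)
  fields <- state_fields(state)
  week <- fields$study_week
  keep <- vapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    slot %in% row$slots[[1]] &&
      phase_active(row$category, week) &&
      eval_rule(row$condition[[1]], fields)
  }, logical(1))
  catalog[keep, ]
}

#' Deterministic message choice among eligibles
#'
#' Highest rule priority first, then the message sent least recently (never
#' sent beats ever sent), then the lexicographically lowest message id, so
#' a replayed schedule is bit-identical across runs.
#'
#' @param eligible Eligible catalog rows ([eligible_messages()]).
#' @param history Character vector of previously sent message ids in send
#'   order (most recent last).
#' @return A one-row catalog tibble, or `NULL` when nothing is eligible.
#' @export
select_message <- function(eligible, history = character(0)) {
  if (is.null(eligible) || nrow(eligible) == 0) return(NULL)
  last_sent <- vapply(eligible$message_id, function(id) {
    pos <- which(history == id)
    if (length(pos)) max(pos) else -Inf  # never sent sorts first
  }, numeric(1))
  o <- order(-eligible$priority, last_sent, eligible$message_id)
  eligible[o[1], ]
}

slot_anchor_defaults <- c(after_waking = 7 * 60 + 30, around_noon = 12 * 60,
                          evening = 18 * 60, before_bedtime = 22 * 60 + 30)

slot_anchors <- function(state) {
  anchors <- slot_anchor_defaults
  dh <- state$diary_history
  if (!is.null(dh) && nrow(dh) > 0) {
    last <- dh[which.max(dh$date), ]
    arising <- (last$final_awakening_time + last$bed_out_latency) %% 1440L
    anchors["after_waking"] <- (arising + 30L) %% 1440L
  }
  if (!is.null(state$schedule)) {
    anchors["before_bedtime"] <-
      clock_time(state$schedule$set_bed_time - 60L)
  }
  anchors
}

# Move a candidate time into the nearest receptive window (circular
# distance to the window edge); identity when no windows are declared.
snap_to_windows <- function(t, windows) {
  if (is.null(windows) || nrow(windows) == 0) return(clock_time(t))
  t <- clock_time(t)
  inside <- vapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start[i]; e <- windows$end[i]
    if (s <= e) t >= s && t <= e else t >= s || t <= e  # window may wrap
  }, logical(1))
  if (any(inside)) return(t)
  edges <- c(windows$start, windows$end)
  d <- pmin((edges - t) %% 1440L, (t - edges) %% 1440L)
  edges[which.min(d)]
}

#' Plan one day of prompt deliveries
#'
#' For each of the four daily slots, takes the slot's anchor time (after
#' waking = last recorded arising time + 30 min; around noon = 12:00;
#' evening = 18:00; before bedtime = set bedtime - 60 min), snaps it into
#' the participant's nearest receptive window when windows are declared,
#' and delivers at most one eligible message per slot, at most `daily_cap`
#' in total. Messages sent within the last `cooldown_days` days are
#' withheld so content rotates.
#'
#' @param catalog Catalog tibble.
#' @param state A [participant_state()].
#' @param date Delivery date.
#' @param history Data frame of prior deliveries with columns `date` and
#'   `message_id` (empty by default).
#' @param daily_cap Maximum deliveries per day (default 4, one per slot).
#' @param cooldown_days Repeat-suppression horizon in days (default 7).
#' @return A tibble (`date`, `slot`, `delivery_time`, `message_id`,
#'   `category`), zero rows when nothing is eligible.
#' @export
schedule_day <- function(catalog, state, date, history = NULL,
                         daily_cap = 4L, cooldown_days = 7L) {
  date <- as.Date(date)
  if (is.null(history)) {
    history <- data.frame(date = as.Date(character(0)),
                          message_id = character(0))
  }
  recent <- history$message_id[history$date > date - cooldown_days]
  anchors <- slot_anchors(state)
  plan <- list()
  for (slot in prompt_slots) {
    if (length(plan) >= daily_cap) break
    elig <- eligible_messages(catalog, state, slot)
    elig <- elig[!elig$message_id %in% recent, ]
    pick <- select_message(elig, history$message_id)
    if (is.null(pick)) next
    t <- snap_to_windows(anchors[[slot]], state$receptive_windows)
    plan[[length(plan) + 1L]] <- tibble::tibble(
      date = date, slot = slot, delivery_time = t,
      message_id = pick$message_id, category = pick$category
    )
    recent <- c(recent, pick$message_id)
    history <- rbind(history,
                     data.frame(date = date, message_id = pick$message_id))
  }
  if (length(plan) == 0) {
    return(tibble::tibble(date = as.Date(character(0)), slot = character(0),
                          delivery_time = integer(0), message_id = character(0),
                          category = character(0)))
  }
  dplyr::bind_rows(plan)
}

#' Replay a full 28-day prompt schedule
#'
#' Runs [schedule_day()] over a stream of daily participant states,
#' threading the delivery history (and hence cool-downs) through the whole
#' program. Deterministic: the same catalog and state stream always yield
#' the identical plan.
#'
#' @param catalog Catalog tibble.
#' @param states A list of [participant_state()] objects, one per program
#'   day in order (their `study_day` fields must be 1..length(states)).
#' @param start_date Calendar date of program day 1.
#' @inheritParams schedule_day
#' @return A delivery tibble over all days.
#' @export
replay_program <- function(catalog, states, start_date = as.Date("2021-01-04"),
                           daily_cap = 4L, cooldown_days = 7L) {
  history <- data.frame(date = as.Date(character(0)),
                        message_id = character(0))
  out <- list()
  for (i in seq_along(states)) {
    day_plan <- schedule_day(catalog, states[[i]],
                             date = start_date + i - 1L, history = history,
                             daily_cap = daily_cap,
                             cooldown_days = cooldown_days)
    if (nrow(day_plan)) {
      history <- rbind(history, data.frame(date = day_plan$date,
                                           message_id = day_plan$message_id))
      out[[length(out) + 1L]] <- day_plan
    }
  }
  if (!length(out)) {
    return(schedule_day(catalog, states[[1]], start_date)[0, ])
  }
  dplyr::bind_rows(out)
}

#' Read, write, and ship prompt-message catalogs
#'
#' The catalog is a delimited table with columns `message_id`, `category`,
#' `topic`, `slots` (semicolon-joined slot names), `priority` (integer,
#' larger fires first), `condition` (the rule tree as JSON; empty = always),
#' and `text`. `default_catalog()` loads the seed catalog shipped with the
#' package: ~40 representative messages across the five program components
#' and the sleep-hygiene topics (light, caffeine, exercise, alcohol,
#' napping, bathing, rhythm, and so on). Users supply a full catalog as a
#' file of the same schema.
#'
#' @param path Catalog CSV path.
#' @param catalog A catalog tibble to write.
#' @return A catalog tibble with list-columns `slots` (character vectors)
#'   and `condition` (parsed rule trees).
#' @export
read_catalog <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("message_id", "category", "topic", "slots", "priority",
                "condition", "text")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !raw$category %in% prompt_categories
  if (any(bad)) {
    stop("unknown catalog category: ",
         paste(unique(raw$category[bad]), collapse = ", "), call. = FALSE)
  }
  slots <- strsplit(raw$slots, ";", fixed = TRUE)
  if (any(lengths(slots) == 0) ||
      !all(unlist(slots) %in% prompt_slots)) {
    stop("each message needs at least one valid slot", call. = FALSE)
  }
  cond <- lapply(raw$condition, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    jsonlite::fromJSON(s, simplifyVector = FALSE)
  })
  tibble::tibble(
    message_id = raw$message_id, category = raw$category, topic = raw$topic,
    slots = slots, priority = as.integer(raw$priority), condition = cond,
    text = raw$text
  )
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  out <- data.frame(
    message_id = catalog$message_id, category = catalog$category,
    topic = catalog$topic,
    slots = vapply(catalog$slots, paste, "", collapse = ";"),
    priority = catalog$priority,
    condition = vapply(catalog$condition, function(x) {
      if (is.null(x)) "" else
        as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
    }, ""),
    text = catalog$text, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_catalog
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "prompt_catalog.csv",
                           package = "promptsleep", mustWork = TRUE))
}
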