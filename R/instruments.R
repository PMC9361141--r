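check_items <- function(items, n, lo, hi, what) {
  items <- as.integer(items)
  if (length(items) != n) {
    stop(what, " requires exactly ", n, " items, got ", length(items),
         call. = FALSE)
  }
  if (anyNA(items)) {
    stop(what, " has missing items; responses with missing items score ",
         "as missing (no prorating)", call. = FALSE)
  }
  if (any(items < lo | items > hi)) {
    stop(what, " items must be integers in ", lo, "..", hi, call. = FALSE)
  }
  items
}

#' Score the Insomnia Severity Index
#'
#' Sum of the 7 items, each 0-4, giving a total from 0 (no insomnia) to 28
#' (severe insomnia). No imputation: any missing item makes the response
#' unscorable.
#'
#' @param items Integer vector of 7 item responses in 0..4.
#' @return Integer total in `[0, 28]`.
#' @export
score_isi <- function(items) {
  sum(check_items(items, 7L, 0L, 4L, "ISI"))
}

#' Classify an ISI total
#'
#' Two cutoffs drive the study design: a total of 8 or more defines an
#' "ISI-8 insomniac", and the randomization strata split totals into
#' `<8`, `8-14`, and `>=15`.
#'
#' @param total ISI total(s) in `[0, 28]`.
#' @return A tibble with columns `total`, `insomniac` (`"isi8_insomniac"` /
#'   `"non_insomniac"`), and `stratum` (`"lt8"`, `"s8_14"`, `"ge15"`).
#' @export
isi_classify <- function(total) {
  total <- as.integer(total)
  if (any(is.na(total) | total < 0 | total > 28)) {
    stop("ISI totals must be integers in 0..28", call. = FALSE)
  }
  tibble::tibble(
    total = total,
    insomniac = ifelse(total >= 8, "isi8_insomniac", "non_insomniac"),
    stratum = ifelse(total < 8, "lt8", ifelse(total < 15, "s8_14", "ge15"))
  )
}

#' Score the Chalder Fatigue Scale (Likert scoring)
#'
#' Each of the 11 items is scored 0-3 from the least to the most
#' symptomatic response. The global score (0-33) splits into a physical
#' subscale (items 1-7, 0-21) and a psychological subscale (items 8-11,
#' 0-12); the subscales always reconstitute the total. Only Likert scoring
#' is provided; bimodal CFS scoring is deliberately not implemented.
#'
#' @param items Integer vector of 11 item responses in 0..3.
#' @return A named list: `global`, `physical`, `psychological`.
#' @export
score_cfs <- function(items) {
  items <- check_items(items, 11L, 0L, 3L, "CFS")
  list(global = sum(items), physical = sum(items[1:7]),
       psychological = sum(items[8:11]))
}

#' HPQ relative presenteeism
#'
#' The ratio of self-rated actual work performance over the past 4 weeks
#' (item B11, 0-10) to the rated performance of most workers in the same
#' job (item B9, 0-10), bounded to the instrument's scale: 0.25 is the
#' worst relative performance (a quarter or less of other workers'), 2.0
#' the best (double or more). A comparator rating of 0 leaves the ratio
#' undefined and the value is returned as missing.
#'
#' @param b11 Actual performance in the past 4 weeks, 0..10.
#' @param b9 Performance of most workers in the same job, 0..10.
#' @return Numeric in `[0.25, 2]`, or `NA` when `b9` is 0.
#' @export
relative_presenteeism <- function(b11, b9) {
  stopifnot(all(b11 >= 0 & b11 <= 10, na.rm = TRUE),
            all(b9 >= 0 & b9 <= 10, na.rm = TRUE))
  ifelse(b9 == 0, NA_real_, pmin(pmax(b11 / b9, 0.25), 2.0))
}

#' HPQ absolute presenteeism
#'
#' Ten times the self-rated actual performance, on a 0-100 scale. The
#' instrument's short form labels the formula with the 1-2-year recall
#' wording but the item code B11 (the 4-week self-rating); this follows the
#' standard HPQ convention and uses B11.
#'
#' @param b11 Actual performance in the past 4 weeks, 0..10.
#' @return Numeric in `[0, 100]`.
#' @export
absolute_presenteeism <- function(b11) {
  stopifnot(all(b11 >= 0 & b11 <= 10, na.rm = TRUE))
  10 * b11
}

#' Daily caffeine intake in milligrams
#'
#' Computed from reported cups per day at 95 mg per cup of coffee, 55 mg
#' per cup of tea, and 45 mg per cup of cola.
#'
#' @param cups_coffee,cups_tea,cups_cola Cups per day (>= 0).
#' @return Milligrams of caffeine per day.
#' @export
caffeine_mg <- function(cups_coffee, cups_tea, cups_cola) {
  stopifnot(all(cups_coffee >= 0), all(cups_tea >= 0), all(cups_cola >= 0))
  95 * cups_coffee + 55 * cups_tea + 45 * cups_cola
}

#' Body-mass index and the obesity cutoff
#'
#' @param weight_kg Weight in kilograms (> 0).
#' @param height_cm Height in centimetres (> 0).
#' @return A tibble with `bmi` (kg/m^2) and `obese` (`TRUE` iff BMI >= 25,
#'   cutoff inclusive).
#' @export
bmi_obese <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  bmi <- weight_kg / (height_cm / 100)^2
  tibble::tibble(bmi = bmi, obese = bmi >= 25)
}

#' Score the PHQ-9 depression screen
#'
#' @param items Integer vector of 9 item responses in 0..3.
#' @return Integer total in `[0, 27]`.
#' @export
score_phq9 <- function(items) {
  sum(check_items(items, 9L, 0L, 3L, "PHQ-9"))
}

#' Eligibility screen for the worker cohort
#'
#' Applies the trial's inclusion criteria (worker aged 20 or older, owns a
#' smartphone, affirms having a sleep problem) and exclusion criteria
#' (unsupported device, shift work, expected major time-zone travel, PHQ-9
#' total of 10 or more, or self-harm thoughts — PHQ-9 item 9 — on more than
#' half of the days, i.e. a response code of 2 or 3).
#'
#' @param age Years.
#' @param has_smartphone,has_sleep_problem Logical inclusions.
#' @param phq9_items The 9 PHQ-9 item responses (0..3 each).
#' @param shift_worker,timezone_travel Logical exclusions.
#' @param device_supported Whether the phone supports the app.
#' @return A list: `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, empty when eligible).
#' @export
screen_eligibility <- function(age, has_smartphone, has_sleep_problem,
                               phq9_items, shift_worker, timezone_travel,
                               device_supported) {
  args <- list(age = age, has_smartphone = has_smartphone,
               has_sleep_problem = has_sleep_problem,
               shift_worker = shift_worker,
               timezone_travel = timezone_travel,
               device_supported = device_supported)
  for (nm in names(args)) {
    if (length(args[[nm]]) != 1 || is.na(args[[nm]])) {
      stop("screening field '", nm, "' is missing", call. = FALSE)
    }
  }
  phq9_items <- check_items(phq9_items, 9L, 0L, 3L, "PHQ-9")
  reasons <- character(0)
  if (age < 20) reasons <- c(reasons, "inclusion: age under 20")
  if (!has_smartphone) reasons <- c(reasons, "inclusion: no smartphone")
  if (!has_sleep_problem) {
    reasons <- c(reasons, "inclusion: no self-reported sleep problem")
  }
  if (!device_supported) reasons <- c(reasons, "exclusion: unsupported device")
  if (shift_worker) reasons <- c(reasons, "exclusion: shift worker")
  if (timezone_travel) {
    reasons <- c(reasons, "exclusion: expected time-zone travel")
  }
  if (sum(phq9_items) >= 10) {
    reasons <- c(reasons, "exclusion: PHQ-9 total >= 10")
  }
  if (phq9_items[9] >= 2) {
    reasons <- c(reasons,
                 "exclusion: self-harm thoughts more than half the days")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Score a tidy table of item-level instrument responses
#'
#' Input rows carry `participant_id`, `instrument` (`"isi"`, `"cfs"`,
#' `"phq9"`, or `"hpq"`), `week`, and item columns `item_1` ... `item_k`
#' (unused trailing items `NA`). For the HPQ, items 1-3 are B9, B10, B11.
#' Returns one row per score in long form.
#'
#' @param responses A data frame as described.
#' @return A tibble (`participant_id`, `week`, `measure`, `value`).
#' @export
score_responses <- function(responses) {
  item_cols <- grep("^item_", names(responses), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    r <- responses[i, ]
    items <- as.numeric(r[item_cols])
    items <- items[!is.na(items)]
    base <- function(measure, value) {
      tibble::tibble(participant_id = r$participant_id, week = r$week,
                     measure = measure, value = value)
    }
    switch(tolower(r$instrument),
      isi = base("isi_total", score_isi(items)),
      phq9 = base("phq9_total", score_phq9(items)),
      cfs = {
        s <- score_cfs(items)
        dplyr::bind_rows(base("cfs_global", s$global),
                         base("cfs_physical", s$physical),
                         base("cfs_psychological", s$psychological))
      },
      hpq = {
        if (length(items) != 3) {
          stop("HPQ rows need items 1-3 = B9, B10, B11", call. = FALSE)
        }
        dplyr::bind_rows(
          base("relative_presenteeism",
               relative_presenteeism(b11 = items[3], b9 = items[1])),
          base("absolute_presenteeism", absolute_presenteeism(items[3]))
        )
      },
      stop("unknown instrument '", r$instrument, "'", call. = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}
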