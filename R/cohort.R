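#' Configuration for the synthetic worker cohort
#'
#' Collects every knob of the simulator with defaults calibrated to the
#' study conditions: a two-arm cohort of workers with mild insomnia
#' (baseline ISI mean 9.2), a control arm declining 0.3 ISI points per
#' week and an intervention arm declining 0.3 points per week faster
#' (group means 9.2 to 8.0 vs 9.2 to 6.8 over four weeks), diary timing
#' centred on a 23:30 bedtime and 06:30 desired wake time, log-normal
#' sleep-onset latencies, occasional missing diary days, a small upward
#' sleep-efficiency drift per restriction week in the intervention arm,
#' and a post-allocation dropout risk matching the observed 2-of-62
#' app-installation failures.
#'
#' @param n_per_arm Target participants per arm (>= 2).
#' @param baseline_isi_mean,baseline_isi_sd Latent baseline ISI
#'   distribution (points).
#' @param weekly_decline_control Control-arm ISI trend, points/week
#'   (negative = improvement).
#' @param extra_decline_spa Additional intervention-arm trend, points/week.
#' @param isi_noise_sd Residual SD of weekly ISI observations (points).
#' @param bedtime_mean,bedtime_sd Habitual bedtime (clock) and night-to-night
#'   jitter SD (minutes).
#' @param wake_time_mean,wake_time_sd Desired wake time and jitter SD.
#' @param sol_meanlog,sol_sdlog Log-normal sleep-onset latency parameters
#'   (minutes scale; defaults give a ~20 min median).
#' @param waso_mean,waso_sd Wake after sleep onset, normal truncated at 0.
#' @param bol_mean,bol_sd Bed-out latency, normal truncated at 0.
#' @param diary_missing_rate Probability a diary day is not recorded.
#' @param titration_response Sleep-efficiency gain (percentage points) per
#'   completed restriction week in the intervention arm.
#' @param dropout_rate Post-allocation dropout probability in the
#'   intervention arm (installation failures).
#' @param female_rate Proportion female.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_arm = 58L,
                          baseline_isi_mean = 9.2, baseline_isi_sd = 3.0,
                          weekly_decline_control = -0.3,
                          extra_decline_spa = -0.3,
                          isi_noise_sd = 2.5,
                          bedtime_mean = "23:30", bedtime_sd = 30,
                          wake_time_mean = "06:30", wake_time_sd = 20,
                          sol_meanlog = log(20), sol_sdlog = 0.5,
                          waso_mean = 20, waso_sd = 15,
                          bol_mean = 10, bol_sd = 5,
                          diary_missing_rate = 0.1,
                          titration_response = 2,
                          dropout_rate = 2 / 62,
                          female_rate = 0.33) {
  cfg <- list(
    n_per_arm = as.integer(n_per_arm),
    baseline_isi_mean = baseline_isi_mean,
    baseline_isi_sd = baseline_isi_sd,
    weekly_decline_control = weekly_decline_control,
    extra_decline_spa = extra_decline_spa,
    isi_noise_sd = isi_noise_sd,
    bedtime_mean = clock_time(bedtime_mean), bedtime_sd = bedtime_sd,
    wake_time_mean = clock_time(wake_time_mean), wake_time_sd = wake_time_sd,
    sol_meanlog = sol_meanlog, sol_sdlog = sol_sdlog,
    waso_mean = waso_mean, waso_sd = waso_sd,
    bol_mean = bol_mean, bol_sd = bol_sd,
    diary_missing_rate = diary_missing_rate,
    titration_response = titration_response,
    dropout_rate = dropout_rate, female_rate = female_rate
  )
  if (cfg$n_per_arm < 2) stop("n_per_arm must be at least 2", call. = FALSE)
  rates <- c(cfg$diary_missing_rate, cfg$dropout_rate, cfg$female_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]",
                                       call. = FALSE)
  sds <- c(cfg$baseline_isi_sd, cfg$isi_noise_sd, cfg$bedtime_sd,
           cfg$wake_time_sd, cfg$waso_sd, cfg$bol_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Named substream so each component of the simulation is independently
# reproducible from one master seed.
substream_seed <- function(seed, stream) {
  offsets <- c(cohort = 1L, randomize = 2L, trajectory = 3L, diary = 4L,
               instruments = 5L, dropout = 6L)
  # arithmetic in doubles so large master seeds cannot overflow integers
  as.integer((as.numeric(seed) * 131 + offsets[[stream]] * 7919) %%
               .Machine$integer.max)
}

#' Generate a virtual enrollment roster
#'
#' Draws demographics, latent and observed baseline ISI (the observed value
#' is the latent intercept plus one residual draw, rounded and truncated to
#' an integer in 0..28), lifestyle habit flags, a desired wake time, and
#' one evening receptive window per participant. Deterministic under the
#' seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A tibble with one row per participant, in arrival order,
#'   including a `receptive_windows` list-column.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  n <- 2L * config$n_per_arm
  withr::with_seed(substream_seed(seed, "cohort"), {
    sex <- ifelse(stats::runif(n) < config$female_rate, "female", "male")
    age <- pmin(pmax(round(stats::rnorm(n, 41, 11)), 20L), 65L)
    latent <- stats::rnorm(n, config$baseline_isi_mean,
                           config$baseline_isi_sd)
    observed <- clamp_isi(latent + stats::rnorm(n, 0, config$isi_noise_sd))
    habits <- tibble::tibble(
      caffeine = stats::runif(n) < 0.7,
      alcohol = stats::runif(n) < 0.65,
      smoking = stats::runif(n) < 0.06,
      hypnotic_use = stats::runif(n) < 0.05
    )
    wake <- clock_time(round(stats::rnorm(n, config$wake_time_mean,
                                          config$wake_time_sd)))
    win_start <- clock_time(round(stats::rnorm(n, 19 * 60, 45)))
  })
  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    sex = sex, age = age,
    baseline_isi_latent = latent, baseline_isi = observed,
    caffeine = habits$caffeine, alcohol = habits$alcohol,
    smoking = habits$smoking, hypnotic_use = habits$hypnotic_use,
    desired_wake_time = wake,
    receptive_windows = lapply(win_start, function(s) {
      data.frame(start = s, end = clock_time(s + 180L))
    })
  )
}

clamp_isi <- function(x) as.integer(pmin(pmax(round(x), 0L), 28L))

trunc0 <- function(x) as.integer(pmax(round(x), 0L))

#' Simulate one participant's 28-day diary stream
#'
#' Nightly bed and wake times jitter around the participant's schedule;
#' sleep-onset latency is log-normal; wake after sleep onset and bed-out
#' latency are truncated normal; days go unrecorded at the configured
#' missing rate. When `restriction_weeks > 0` (intervention arm, weeks
#' 2-4), sleep-onset latency and wake after sleep onset shrink so that
#' sleep efficiency drifts up by about `titration_response` percentage
#' points per completed restriction week. Entries are guaranteed to pass
#' diary validation.
#'
#' @param participant_id Identifier.
#' @param bed_time,wake_time Scheduled bed and wake clock times.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this stream.
#' @param n_days Days to simulate (default 28).
#' @param restriction_weeks Function of the day's week index giving the
#'   number of completed restriction weeks (default 0, i.e. no titration
#'   drift).
#' @param start_date Calendar date of day 1.
#' @return A validated diary tibble with up to `n_days` rows.
#' @export
simulate_diary_stream <- function(participant_id, bed_time, wake_time,
                                  config = cohort_config(), seed = 1L,
                                  n_days = 28L,
                                  restriction_weeks = function(week) 0L,
                                  start_date = as.Date("2021-01-04")) {
  bed_time <- clock_time(bed_time)
  wake_time <- clock_time(wake_time)
  withr::with_seed(seed, {
    recorded <- stats::runif(n_days) >= config$diary_missing_rate
    bed <- clock_time(round(stats::rnorm(n_days, 0, config$bedtime_sd)) +
                        bed_time)
    wake <- clock_time(round(stats::rnorm(n_days, 0, config$wake_time_sd)) +
                         wake_time)
    sol <- trunc0(stats::rlnorm(n_days, config$sol_meanlog, config$sol_sdlog))
    waso <- trunc0(stats::rnorm(n_days, config$waso_mean, config$waso_sd))
    bol <- trunc0(stats::rnorm(n_days, config$bol_mean, config$bol_sd))
    nap <- trunc0(stats::rnorm(n_days, 5, 15))
    n_awake <- ifelse(waso > 0, 1L + stats::rpois(n_days, 1), 0L)
  })
  day <- seq_len(n_days)
  week <- ((day - 1L) %/% 7L) + 1L
  rw <- vapply(week, restriction_weeks, numeric(1))
  tib <- clock_diff(bed, wake)
  # efficiency drift: remove waste minutes worth `titration_response` SE
  # points per completed restriction week, proportionally from SOL and WASO
  target_cut <- config$titration_response / 100 * tib * rw
  waste <- sol + waso
  shrink <- ifelse(waste > 0, pmax(0, 1 - target_cut / waste), 1)
  sol <- trunc0(sol * shrink)
  waso <- trunc0(waso * shrink)
  n_awake <- ifelse(waso > 0, pmax(n_awake, 1L), 0L)
  # keep entries valid: arising must differ from bedtime, latencies must
  # fit inside the bed interval
  bol <- pmin(bol, pmax(tib - sol - waso - 1L, 0L))
  ok <- recorded & tib > 0 & (sol + waso + bol) <= tib &
    ((wake + bol) %% 1440L) != bed
  entries <- tibble::tibble(
    participant_id = as.character(participant_id),
    date = start_date + day - 1L,
    is_holiday = weekdays(start_date + day - 1L) %in%
      c("Saturday", "Sunday"),
    bed_time = bed,
    sleep_onset_latency = sol,
    n_awakenings = as.integer(n_awake),
    awakening_duration = waso,
    final_awakening_time = wake,
    bed_out_latency = as.integer(bol),
    nap_duration = nap,
    sleepiness_times = lapply(seq_len(n_days), function(i) integer(0)),
    alcohol = FALSE, caffeine = FALSE, smoking = FALSE, hypnotic_use = FALSE
  )[ok, ]
  validate_diary(entries)
}

#' Simulate a complete two-arm trial
#'
#' The full pipeline at desk scale: generates a roster
#' ([generate_cohort()]), randomizes it with stratified permuted blocks
#' ([stratified_block_randomize()]), draws weekly ISI trajectories from the
#' random-intercept linear-trend model
#' `isi = intercept_i + week * (decline + is_spa * extra) + noise` (rounded
#' and truncated to integers in 0..28), applies intervention-arm dropout,
#' and optionally simulates intervention-arm diaries with the weekly
#' sleep-restriction titration applied between weeks. The output feeds the
#' trial-design and analysis functions unchanged.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; all randomness descends from it through
#'   named substreams.
#' @param include_diaries Simulate intervention-arm diaries and weekly
#'   titration (default `TRUE`; disable for large calibration runs where
#'   only the ISI trajectories matter).
#' @return A list: `roster` (with arms), `isi_records` (tidy
#'   participant x week ISI, dropouts contributing baseline only),
#'   `diaries`, `schedules`, `consort`, and `config`.
#' @export
simulate_trial <- function(config = cohort_config(), seed = 1L,
                           include_diaries = TRUE) {
  roster <- generate_cohort(config, seed)
  roster <- stratified_block_randomize(
    roster[c("participant_id", "sex", "baseline_isi")],
    seed = substream_seed(seed, "randomize")
  ) |>
    dplyr::left_join(
      roster[setdiff(names(roster), c("sex", "baseline_isi"))],
      by = "participant_id"
    )

  n <- nrow(roster)
  is_spa <- roster$arm == "SPA"
  slope <- config$weekly_decline_control + is_spa * config$extra_decline_spa

  withr::with_seed(substream_seed(seed, "trajectory"), {
    noise <- matrix(stats::rnorm(n * 4L, 0, config$isi_noise_sd), nrow = n)
  })
  isi <- cbind(roster$baseline_isi,
               vapply(1:4, function(w) {
                 clamp_isi(roster$baseline_isi_latent + w * slope +
                             noise[, w])
               }, integer(n)))

  withr::with_seed(substream_seed(seed, "dropout"), {
    dropped <- is_spa & stats::runif(n) < config$dropout_rate
  })

  isi_records <- tibble::tibble(
    participant_id = rep(roster$participant_id, each = 5L),
    arm = rep(roster$arm, each = 5L),
    week = rep(0:4, times = n),
    isi = as.integer(t(isi))
  )
  # dropouts (installation failures) contribute no post-baseline data
  keep <- !(rep(dropped, each = 5L) & isi_records$week > 0)
  isi_records <- isi_records[keep, ]

  diaries <- NULL; schedules <- NULL
  if (include_diaries) {
    diaries <- list(); schedules <- list()
    spa_ids <- which(is_spa & !dropped)
    for (i in spa_ids) {
      pid <- roster$participant_id[i]
      wake <- roster$desired_wake_time[i]
      sched_bed <- config$bedtime_mean
      current <- NULL
      pid_seed <- as.integer(
        (as.numeric(substream_seed(seed, "diary")) + i) %%
          .Machine$integer.max)
      weeks <- list()
      for (w in 1:4) {
        rw_done <- function(week) max(0L, w - 1L)
        wk_entries <- simulate_diary_stream(
          pid, sched_bed, wake, config,
          seed = as.integer((as.numeric(pid_seed) + w * 1009) %%
                              .Machine$integer.max),
          n_days = 7L, restriction_weeks = rw_done,
          start_date = as.Date("2021-01-04") + (w - 1L) * 7L
        )
        weeks[[w]] <- wk_entries
        if (w < 4) {
          summ <- summarize_week(wk_entries, w)
          summ$participant_id <- pid
          current <- tryCatch(
            schedule_next_week(summ, wake, current),
            error = function(e) current
          )
          if (!is.null(current)) {
            sched_bed <- current$set_bed_time
            schedules[[length(schedules) + 1L]] <- current
          }
        }
      }
      diaries[[length(diaries) + 1L]] <- dplyr::bind_rows(weeks)
    }
    diaries <- if (length(diaries)) dplyr::bind_rows(diaries) else NULL
    schedules <- if (length(schedules)) dplyr::bind_rows(schedules) else NULL
  }

  allocated <- c(SPA = sum(is_spa), control = sum(!is_spa))
  consort <- consort_accounting(
    applied = n, eligible = n, allocated = allocated,
    dropouts = c(SPA = sum(dropped), control = 0L),
    dropout_reasons = rep("app installation failure", sum(dropped))
  )
  roster$dropped <- dropped
  list(roster = roster, isi_records = isi_records, diaries = diaries,
       schedules = schedules, consort = consort, config = config,
       seed = seed)
}

#' Export a simulated trial as CSV files
#'
#' Writes the roster/allocation, tidy ISI records, diaries, schedules, and
#' CONSORT flow into a directory using the package's documented CSV
#' schemas, plus a `manifest.json` recording the configuration and seed.
#'
#' @param trial Output of [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roster <- trial$roster
  roster$receptive_windows <- vapply(roster$receptive_windows, function(w) {
    paste(format_clock(w$start), format_clock(w$end), sep = "-")
  }, "")
  roster$desired_wake_time <- format_clock(roster$desired_wake_time)
  utils::write.csv(roster, file.path(dir, "roster.csv"), row.names = FALSE)
  utils::write.csv(trial$isi_records, file.path(dir, "isi_records.csv"),
                   row.names = FALSE)
  if (!is.null(trial$diaries)) {
    write_diary(trial$diaries, file.path(dir, "diaries.csv"))
  }
  if (!is.null(trial$schedules)) {
    write_schedules(trial$schedules, file.path(dir, "schedules.csv"))
  }
  utils::write.csv(trial$consort$flow, file.path(dir, "consort.csv"),
                   row.names = FALSE)
  cfg <- unclass(trial$config)
  jsonlite::write_json(list(seed = trial$seed, config = cfg),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
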