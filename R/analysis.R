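#' Random-intercept longitudinal model for weekly ISI
#'
#' The trial's primary analysis: a linear mixed-effects model of the weekly
#' ISI totals over the five time points (baseline and weeks 1-4) with a
#' random intercept per participant and fixed effects for time, arm, and
#' the time-by-arm interaction. Missing weeks are simply absent — the model
#' uses every observed record and imputes nothing. Estimation is restricted
#' maximum likelihood; fixed-effect p values are two-sided Wald tests with
#' Satterthwaite degrees of freedom (or the normal approximation via
#' `p_method = "wald"`, useful inside large simulation loops).
#'
#' Time is coded as continuous weeks 0-4 with a linear trend by default,
#' so the interaction coefficient is the extra ISI change per week in the
#' intervention arm; `time_coding = "categorical"` refits with week as a
#' factor for a sensitivity analysis (the reported interaction is then the
#' week-4 contrast).
#'
#' @param records A data frame with `participant_id`, `arm` (`"SPA"` /
#'   `"control"`), `week` (0..4), and `isi` (0..28), at most one row per
#'   participant-week.
#' @param time_coding `"linear"` (default) or `"categorical"`.
#' @param p_method `"satterthwaite"` (default) or `"wald"`.
#' @return A list of class `"spa_model_fit"`: `fixed_effects` (tibble of
#'   estimates, SEs, p values), `interaction` (estimate, se, p_value),
#'   `variance_components` (participant intercept SD, residual SD),
#'   `n_obs`, `n_participants`, and the underlying `fit`.
#' @export
fit_longitudinal_model <- function(records,
                                   time_coding = c("linear", "categorical"),
                                   p_method = c("satterthwaite", "wald")) {
  time_coding <- match.arg(time_coding)
  p_method <- match.arg(p_method)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("participant_id", "arm", "week", "isi") %in%
                names(records)))
  if (anyDuplicated(records[c("participant_id", "week")])) {
    stop("at most one record per participant-week", call. = FALSE)
  }
  records$arm <- factor(records$arm, levels = c("control", "SPA"))
  if (any(table(records$arm) == 0)) {
    stop("both arms need observations", call. = FALSE)
  }
  records$time <- if (time_coding == "linear") records$week
                  else factor(records$week)

  fit <- if (p_method == "satterthwaite") {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(isi ~ time * arm + (1 | participant_id),
                     data = records, REML = TRUE)))
  } else {
    suppressMessages(suppressWarnings(
      lme4::lmer(isi ~ time * arm + (1 | participant_id),
                 data = records, REML = TRUE)))
  }
  co <- stats::coef(summary(fit))
  if (p_method == "wald") {
    p <- 2 * stats::pnorm(-abs(co[, "t value"]))
    co <- cbind(co, `Pr(>|t|)` = p)
  }
  fe <- tibble::tibble(
    term = rownames(co), estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    p_value = unname(co[, "Pr(>|t|)"])
  )
  int_term <- if (time_coding == "linear") "time:armSPA" else
    paste0("time", max(records$week), ":armSPA")
  int <- fe[fe$term == int_term, ]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed_effects = fe,
    interaction = list(estimate = int$estimate, se = int$std_error,
                       p_value = int$p_value),
    variance_components = c(
      participant_sd = vc$sdcor[vc$grp == "participant_id"],
      residual_sd = vc$sdcor[vc$grp == "Residual"]
    ),
    n_obs = nrow(records),
    n_participants = length(unique(records$participant_id)),
    time_coding = time_coding, fit = fit
  ), class = "spa_model_fit")
}

#' @export
print.spa_model_fit <- function(x, ...) {
  cat("Random-intercept longitudinal model (", x$time_coding,
      " time), REML\n", sep = "")
  cat(x$n_obs, "observations,", x$n_participants, "participants\n")
  fe <- x$fixed_effects
  fe$estimate <- round(fe$estimate, 3)
  fe$std_error <- round(fe$std_error, 3)
  fe$p_value <- signif(fe$p_value, 2)
  print(as.data.frame(fe), row.names = FALSE)
  cat(sprintf("time x arm interaction: %.3f (p = %.3g)\n",
              x$interaction$estimate, x$interaction$p_value))
  invisible(x)
}

#' Per-arm mean ISI by week
#'
#' Arithmetic means over the available records, the quantity plotted as the
#' trial's weekly trajectory. Full precision is returned; round to one
#' decimal place for presentation.
#'
#' @inheritParams fit_longitudinal_model
#' @return A tibble (`arm`, `week`, `n`, `mean_isi`).
#' @export
weekly_means <- function(records) {
  records <- tibble::as_tibble(records)
  dplyr::summarise(dplyr::group_by(records, arm, week),
                   n = dplyr::n(), mean_isi = mean(isi), .groups = "drop")
}

#' Pre-post change-score table for secondary outcomes
#'
#' For each measure: per-arm mean (SD) at baseline and posttest, the mean
#' (SD) within-arm change, and the between-arm comparison of changes via
#' [two_sample_t_change()] (difference, 95% CI, two-sided p). Participants
#' missing either the baseline or the posttest value for a measure are
#' excluded from that measure with a message.
#'
#' @param scores A tidy data frame: `participant_id`, `arm`, `week`,
#'   `measure`, `value`.
#' @param baseline_week,post_week Week labels of the paired assessments
#'   (defaults 0 and 4).
#' @return A tibble with one row per measure x arm plus the between-arm
#'   columns (`difference`, `conf_low`, `conf_high`, `p_value`) filled on
#'   each measure's first arm row, mirroring the usual table layout.
#' @export
change_score_table <- function(scores, baseline_week = 0, post_week = 4) {
  scores <- tibble::as_tibble(scores)
  out <- list()
  for (m in unique(scores$measure)) {
    sm <- scores[scores$measure == m & scores$week %in%
                   c(baseline_week, post_week), ]
    wide <- merge(
      sm[sm$week == baseline_week, c("participant_id", "arm", "value")],
      sm[sm$week == post_week, c("participant_id", "value")],
      by = "participant_id", suffixes = c("_baseline", "_post")
    )
    n_unpaired <- length(unique(sm$participant_id)) - nrow(wide)
    if (n_unpaired > 0) {
      message(n_unpaired, " participant(s) without paired values excluded ",
              "for measure '", m, "'")
    }
    wide$change <- wide$value_post - wide$value_baseline
    chg <- split(wide$change, factor(wide$arm, levels = c("SPA", "control")))
    cmp <- two_sample_t_change(chg$SPA, chg$control)
    for (arm in c("SPA", "control")) {
      w <- wide[wide$arm == arm, ]
      first <- arm == "SPA"
      out[[length(out) + 1L]] <- tibble::tibble(
        measure = m, arm = arm, n = nrow(w),
        baseline_mean = mean(w$value_baseline),
        baseline_sd = stats::sd(w$value_baseline),
        post_mean = mean(w$value_post), post_sd = stats::sd(w$value_post),
        change_mean = mean(w$change), change_sd = stats::sd(w$change),
        difference = if (first) cmp$difference else NA_real_,
        conf_low = if (first) cmp$conf_int[1] else NA_real_,
        conf_high = if (first) cmp$conf_int[2] else NA_real_,
        p_value = if (first) cmp$p_value else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}
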