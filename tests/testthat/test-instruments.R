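test_that("ISI scores sum the items and the cutoffs are inclusive", {
  expect_equal(score_isi(rep(0, 7)), 0)
  expect_equal(score_isi(rep(4, 7)), 28)
  expect_equal(score_isi(c(2, 2, 1, 1, 1, 1, 0)), 8)
  expect_error(score_isi(c(2, 2, 1, 1, 1, 1)), "exactly 7")
  expect_error(score_isi(c(5, rep(0, 6))), "0..4")
  expect_error(score_isi(c(NA, rep(1, 6))), "missing")

  cls <- isi_classify(c(7, 8, 14, 15, 0, 28))
  expect_equal(cls$insomniac,
               c("non_insomniac", rep("isi8_insomniac", 3),
                 "non_insomniac", "isi8_insomniac"))
  expect_equal(cls$stratum, c("lt8", "s8_14", "s8_14", "ge15", "lt8", "ge15"))
  # classification agrees with brute-force cuts over the whole scale
  all_cls <- isi_classify(0:28)
  expect_equal(all_cls$insomniac == "isi8_insomniac", 0:28 >= 8)
  expect_equal(all_cls$stratum,
               ifelse(0:28 < 8, "lt8", ifelse(0:28 < 15, "s8_14", "ge15")))
})

test_that("CFS subscales reconstitute the global score", {
  expect_equal(score_cfs(rep(0, 11)), list(global = 0, physical = 0,
                                           psychological = 0))
  expect_equal(score_cfs(rep(3, 11)), list(global = 33, physical = 21,
                                           psychological = 12))
  expect_equal(score_cfs(c(rep(1, 7), rep(0, 4))),
               list(global = 7, physical = 7, psychological = 0))
  set.seed(5)
  for (i in 1:25) {
    items <- sample(0:3, 11, replace = TRUE)
    s <- score_cfs(items)
    expect_equal(s$global, s$physical + s$psychological)
    expect_equal(s$global, sum(items))
  }
  expect_error(score_cfs(rep(4, 11)), "0..3")
})

test_that("relative presenteeism is the bounded B11/B9 ratio", {
  expect_equal(relative_presenteeism(8, 8), 1.0)
  expect_equal(relative_presenteeism(1, 10), 0.25)  # floor
  expect_equal(relative_presenteeism(10, 4), 2.0)   # ceiling
  expect_equal(relative_presenteeism(6, 8), 0.75)
  expect_true(is.na(relative_presenteeism(5, 0)))   # undefined comparator
  # clipping is idempotent: re-deriving from a clipped ratio is stable
  r <- relative_presenteeism(1, 10)
  expect_equal(pmin(pmax(r, 0.25), 2.0), r)
})

test_that("absolute presenteeism is 10 x B11 on a 0-100 scale", {
  expect_equal(absolute_presenteeism(6), 60)
  expect_equal(absolute_presenteeism(0), 0)
  expect_equal(absolute_presenteeism(10), 100)
  expect_error(absolute_presenteeism(11))
})

test_that("caffeine and BMI follow the stated conversions", {
  expect_equal(caffeine_mg(1, 0, 0), 95)
  expect_equal(caffeine_mg(0, 0, 0), 0)
  expect_equal(caffeine_mg(2, 1, 0), 245)
  expect_equal(caffeine_mg(1, 2, 3), 95 + 110 + 135)

  b <- bmi_obese(100, 200)
  expect_equal(b$bmi, 25)
  expect_true(b$obese)  # >= 25 inclusive
  b2 <- bmi_obese(60, 170)
  expect_equal(round(b2$bmi, 2), 20.76)
  expect_false(b2$obese)
  expect_error(bmi_obese(0, 170), "positive")
})

test_that("the eligibility screen applies every criterion with reasons", {
  ok_phq <- rep(0, 9)
  base <- list(age = 30, has_smartphone = TRUE, has_sleep_problem = TRUE,
               phq9_items = ok_phq, shift_worker = FALSE,
               timezone_travel = FALSE, device_supported = TRUE)
  expect_true(do.call(screen_eligibility, base)$eligible)

  underage <- base; underage$age <- 19
  r <- do.call(screen_eligibility, underage)
  expect_false(r$eligible)
  expect_match(r$reasons, "age", all = FALSE)

  # PHQ-9 total of exactly 10 excludes
  dep <- base; dep$phq9_items <- c(2, 2, 2, 2, 2, 0, 0, 0, 0)
  expect_equal(score_phq9(dep$phq9_items), 10)
  expect_false(do.call(screen_eligibility, dep)$eligible)
  # ... but 9 does not
  dep$phq9_items <- c(2, 2, 2, 2, 1, 0, 0, 0, 0)
  expect_true(do.call(screen_eligibility, dep)$eligible)

  # item 9 at "more than half the days" excludes regardless of total
  harm <- base; harm$phq9_items <- c(1, 1, 1, 1, 0, 0, 0, 0, 2)
  r2 <- do.call(screen_eligibility, harm)
  expect_false(r2$eligible)
  expect_match(r2$reasons, "self-harm", all = FALSE)

  shift <- base; shift$shift_worker <- TRUE
  expect_false(do.call(screen_eligibility, shift)$eligible)
  missing_field <- base; missing_field$age <- NA
  expect_error(do.call(screen_eligibility, missing_field), "missing")
})

test_that("item-level responses score into the tidy measure table", {
  responses <- tibble::tibble(
    participant_id = c("p01", "p01", "p02"),
    instrument = c("isi", "cfs", "hpq"),
    week = c(0, 0, 4),
    item_1 = c(2, 1, 8), item_2 = c(2, 1, 7), item_3 = c(1, 1, 6),
    item_4 = c(1, 1, NA), item_5 = c(1, 1, NA), item_6 = c(1, 1, NA),
    item_7 = c(0, 1, NA), item_8 = c(NA, 0, NA), item_9 = c(NA, 0, NA),
    item_10 = c(NA, 0, NA), item_11 = c(NA, 0, NA)
  )
  scored <- score_responses(responses)
  expect_equal(scored$value[scored$measure == "isi_total"], 8)
  expect_equal(scored$value[scored$measure == "cfs_global"], 7)
  expect_equal(scored$value[scored$measure == "cfs_psychological"], 0)
  expect_equal(scored$value[scored$measure == "relative_presenteeism"],
               6 / 8)
  expect_equal(scored$value[scored$measure == "absolute_presenteeism"], 60)
})
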